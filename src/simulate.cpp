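// Core Brownian-dynamics engine: screened Bessel-K1 attraction, birth/death
// sweeps, hard-core admissibility, uniform hash grids for neighbor search.
// All random numbers come from R's RNG so runs are reproducible via set.seed().

#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <cmath>
#include <cstdint>

using namespace Rcpp;

// relative slack on squared-distance threshold comparisons, so that points at
// distance exactly 1 constructed from irrational coordinates still count as
// "<= 1" (inclusive contact rule)
static const double REL_EPS = 1e-9;

// ---------------------------------------------------------------------------
// uniform hash grid over the unbounded plane
struct Grid {
  double cell;
  std::unordered_map<int64_t, std::vector<int>> bins;

  static int64_t key(int ix, int iy) {
    return (static_cast<int64_t>(ix) << 32) ^
           static_cast<int64_t>(static_cast<uint32_t>(iy));
  }
  int bi(double v) const { return static_cast<int>(std::floor(v / cell)); }
  void insert(int idx, double x, double y) {
    bins[key(bi(x), bi(y))].push_back(idx);
  }
  void remove(int idx, double x, double y) {
    auto it = bins.find(key(bi(x), bi(y)));
    if (it == bins.end()) return;
    std::vector<int> &v = it->second;
    for (size_t k = 0; k < v.size(); ++k)
      if (v[k] == idx) { v[k] = v.back(); v.pop_back(); return; }
  }
  void clear() { bins.clear(); }
};

struct Params {
  double delta, sigma, cutoff, birth_rate, death_rate, diffusion, dt,
      overlap_floor;
  int max_retries;
};

// force-magnitude table: coef(r) such that force on i = coef(r) * (r_j - r_i).
// coef(r) = (delta/sigma) * K1(r/sigma) / r, truncated at the cutoff.
struct ForceTable {
  double delta, sigma, cutoff, rmin, dr;
  std::vector<double> A;

  void build(double delta_, double sigma_, double cutoff_, int n = 16384) {
    delta = delta_; sigma = sigma_; cutoff = cutoff_;
    rmin = 0.05;
    if (cutoff <= rmin) cutoff = rmin * 2;
    dr = (cutoff - rmin) / (n - 1);
    A.assign(n, 0.0);
    if (delta > 0)
      for (int k = 0; k < n; ++k) {
        double r = rmin + k * dr;
        A[k] = (delta / sigma) * ::Rf_bessel_k(r / sigma, 1.0, 1.0) / r;
      }
  }
  double coef(double r) const {
    if (delta <= 0 || r >= cutoff) return 0.0;
    if (r <= rmin) return A[0];
    double u = (r - rmin) / dr;
    int k = static_cast<int>(u);
    if (k >= static_cast<int>(A.size()) - 1) k = A.size() - 2;
    double w = u - k;
    return A[k] * (1.0 - w) + A[k + 1] * w;
  }
};

// ---------------------------------------------------------------------------
struct State {
  Params p;
  bool use_table;
  ForceTable ft;
  std::vector<double> x, y;
  std::vector<int> id;
  std::vector<char> alive;
  int na;        // alive count
  int n_dead;    // dead slots awaiting compaction
  int next_id;
  Grid fine, coarse;

  void init_grids() {
    fine.cell = std::max(p.overlap_floor, 1e-6);
    coarse.cell = std::max(p.cutoff / 3.0, fine.cell);
  }
  void rebuild_grids() {
    fine.clear(); coarse.clear();
    for (size_t i = 0; i < x.size(); ++i)
      if (alive[i]) { fine.insert(i, x[i], y[i]); coarse.insert(i, x[i], y[i]); }
  }
  double pair_coef(double r) const {
    if (p.delta <= 0 || r >= p.cutoff) return 0.0;
    if (use_table) return ft.coef(r);
    return (p.delta / p.sigma) * ::Rf_bessel_k(r / p.sigma, 1.0, 1.0) / r;
  }
  bool admissible(double cx, double cy, int ignore) const {
    double f2 = p.overlap_floor * p.overlap_floor;
    int ix = fine.bi(cx), iy = fine.bi(cy);
    for (int ax = ix - 1; ax <= ix + 1; ++ax)
      for (int ay = iy - 1; ay <= iy + 1; ++ay) {
        auto it = fine.bins.find(Grid::key(ax, ay));
        if (it == fine.bins.end()) continue;
        for (int j : it->second) {
          if (j == ignore || !alive[j]) continue;
          double dx = x[j] - cx, dy = y[j] - cy;
          if (dx * dx + dy * dy < f2 * (1.0 - REL_EPS)) return false;
        }
      }
    return true;
  }
  void drift(int i, double &fx, double &fy) const {
    fx = 0.0; fy = 0.0;
    if (p.delta <= 0) return;
    double c2 = p.cutoff * p.cutoff;
    int r = static_cast<int>(std::ceil(p.cutoff / coarse.cell));
    int ix = coarse.bi(x[i]), iy = coarse.bi(y[i]);
    for (int ax = ix - r; ax <= ix + r; ++ax)
      for (int ay = iy - r; ay <= iy + r; ++ay) {
        auto it = coarse.bins.find(Grid::key(ax, ay));
        if (it == coarse.bins.end()) continue;
        for (int j : it->second) {
          if (j == i || !alive[j]) continue;
          double dx = x[j] - x[i], dy = y[j] - y[i];
          double d2 = dx * dx + dy * dy;
          if (d2 >= c2 || d2 <= 0.0) continue;
          double a = pair_coef(std::sqrt(d2));
          fx += a * dx; fy += a * dy;
        }
      }
  }
  void kill(int i) {
    alive[i] = 0; --na; ++n_dead;
    fine.remove(i, x[i], y[i]);
    coarse.remove(i, x[i], y[i]);
  }
  void death_sweep() {
    double pd = p.death_rate * p.dt;
    if (pd <= 0) return;
    size_t n0 = x.size();
    for (size_t i = 0; i < n0; ++i) {
      if (!alive[i]) continue;
      if (unif_rand() < pd) kill(i);
    }
  }
  void birth_sweep() {
    double pb = p.birth_rate * p.dt;
    if (pb <= 0) return;
    size_t n0 = x.size();   // daughters appended past n0 never divide this sweep
    for (size_t i = 0; i < n0; ++i) {
      if (!alive[i]) continue;
      if (unif_rand() >= pb) continue;
      for (int t = 0; t < p.max_retries; ++t) {
        double th = unif_rand() * 2.0 * M_PI;
        double cx = x[i] + std::cos(th), cy = y[i] + std::sin(th);
        if (admissible(cx, cy, -1)) {
          x.push_back(cx); y.push_back(cy);
          alive.push_back(1); id.push_back(next_id++);
          ++na;
          int idx = static_cast<int>(x.size()) - 1;
          fine.insert(idx, cx, cy); coarse.insert(idx, cx, cy);
          break;
        }
      }
    }
  }
  void move_sweep() {
    double sd = std::sqrt(2.0 * p.diffusion * p.dt);
    size_t n0 = x.size();
    for (size_t i = 0; i < n0; ++i) {
      if (!alive[i]) continue;
      double fx, fy;
      drift(static_cast<int>(i), fx, fy);  // drift fixed; only noise is redrawn
      double bx = x[i] + fx * p.dt, by = y[i] + fy * p.dt;
      for (int t = 0; t < p.max_retries; ++t) {
        double nx = bx + sd * norm_rand(), ny = by + sd * norm_rand();
        if (admissible(nx, ny, static_cast<int>(i))) {
          fine.remove(i, x[i], y[i]); coarse.remove(i, x[i], y[i]);
          x[i] = nx; y[i] = ny;
          fine.insert(i, nx, ny); coarse.insert(i, nx, ny);
          break;
        }
      }
    }
  }
  void maybe_compact() {
    if (n_dead == 0 || n_dead * 4 < static_cast<int>(x.size())) return;
    size_t w = 0;
    for (size_t i = 0; i < x.size(); ++i) {
      if (!alive[i]) continue;
      if (w != i) { x[w] = x[i]; y[w] = y[i]; id[w] = id[i]; }
      ++w;
    }
    x.resize(w); y.resize(w); id.resize(w);
    alive.assign(w, 1);
    n_dead = 0;
    rebuild_grids();
  }
  List config_list(double time) const {
    int n = na;
    NumericVector ox(n), oy(n);
    IntegerVector oid(n);
    int w = 0;
    for (size_t i = 0; i < x.size(); ++i)
      if (alive[i]) { ox[w] = x[i]; oy[w] = y[i]; oid[w] = id[i]; ++w; }
    return List::create(_["x"] = ox, _["y"] = oy, _["id"] = oid,
                        _["time"] = time);
  }
};

static State make_state(NumericVector x, NumericVector y, IntegerVector id,
                        List par, bool use_table) {
  State s;
  s.p.delta = as<double>(par["delta"]);
  s.p.sigma = as<double>(par["sigma"]);
  s.p.cutoff = as<double>(par["cutoff"]);
  s.p.birth_rate = as<double>(par["birth_rate"]);
  s.p.death_rate = as<double>(par["death_rate"]);
  s.p.diffusion = as<double>(par["diffusion"]);
  s.p.dt = as<double>(par["dt"]);
  s.p.overlap_floor = as<double>(par["overlap_floor"]);
  s.p.max_retries = as<int>(par["max_retries"]);
  s.use_table = use_table;
  if (use_table && s.p.delta > 0) s.ft.build(s.p.delta, s.p.sigma, s.p.cutoff);
  int n = x.size();
  s.x.assign(x.begin(), x.end());
  s.y.assign(y.begin(), y.end());
  s.id.assign(id.begin(), id.end());
  s.alive.assign(n, 1);
  s.na = n; s.n_dead = 0;
  s.next_id = 1;
  for (int i = 0; i < n; ++i) if (id[i] >= s.next_id) s.next_id = id[i] + 1;
  s.init_grids();
  s.rebuild_grids();
  return s;
}

// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List death_sweep_cpp(NumericVector x, NumericVector y, IntegerVector id,
                     List par) {
  State s = make_state(x, y, id, par, false);
  s.death_sweep();
  return s.config_list(NA_REAL);
}

// [[Rcpp::export]]
List birth_sweep_cpp(NumericVector x, NumericVector y, IntegerVector id,
                     List par) {
  State s = make_state(x, y, id, par, false);
  s.birth_sweep();
  return s.config_list(NA_REAL);
}

// [[Rcpp::export]]
List move_sweep_cpp(NumericVector x, NumericVector y, IntegerVector id,
                    List par) {
  State s = make_state(x, y, id, par, false);
  s.move_sweep();
  return s.config_list(NA_REAL);
}

// [[Rcpp::export]]
List run_simulation_cpp(NumericVector x0, NumericVector y0, IntegerVector id0,
                        double t0, List par, int n_steps, int snapshot_every) {
  State s = make_state(x0, y0, id0, par, true);
  double dt = s.p.dt;
  std::vector<int> pop;
  pop.reserve(n_steps + 1);
  pop.push_back(s.na);
  List snaps;  // grown via std::vector of Lists
  std::vector<List> snapv;
  bool extinct = (s.na == 0);
  int step = 0;
  while (step < n_steps && !extinct) {
    ++step;
    s.death_sweep();
    if (s.na == 0) { extinct = true; pop.push_back(0); break; }
    s.birth_sweep();
    s.move_sweep();
    s.maybe_compact();
    pop.push_back(s.na);
    if (snapshot_every > 0 && step % snapshot_every == 0 && step < n_steps)
      snapv.push_back(s.config_list(t0 + step * dt));
    if (step % 256 == 0) Rcpp::checkUserInterrupt();
  }
  double t_end = t0 + step * dt;
  List out = List::create(
      _["final"] = s.config_list(t_end), _["extinct"] = extinct,
      _["steps_done"] = step, _["t_end"] = t_end,
      _["population"] = IntegerVector(pop.begin(), pop.end()),
      _["snapshots"] = wrap(snapv));
  return out;
}

// grid = true: cell-list neighbor search with cutoff truncation (tabulated
// force); grid = false: exact all-pairs sum with direct Bessel evaluation and
// no cutoff (the testing oracle mode).
// [[Rcpp::export]]
NumericMatrix net_forces_cpp(NumericVector x, NumericVector y, double delta,
                             double sigma, double cutoff, bool grid) {
  int n = x.size();
  NumericMatrix out(n, 2);
  if (delta <= 0 || n < 2) return out;
  if (grid) {
    List par = List::create(
        _["delta"] = delta, _["sigma"] = sigma, _["cutoff"] = cutoff,
        _["birth_rate"] = 0.0, _["death_rate"] = 0.0, _["diffusion"] = 0.0,
        _["dt"] = 1.0, _["overlap_floor"] = 0.8, _["max_retries"] = 1);
    IntegerVector id = seq_len(n);
    State s = make_state(x, y, id, par, true);
    for (int i = 0; i < n; ++i) {
      double fx, fy;
      s.drift(i, fx, fy);
      out(i, 0) = fx; out(i, 1) = fy;
    }
  } else {
    for (int i = 0; i < n; ++i) {
      double fx = 0, fy = 0;
      for (int j = 0; j < n; ++j) {
        if (j == i) continue;
        double dx = x[j] - x[i], dy = y[j] - y[i];
        double d = std::sqrt(dx * dx + dy * dy);
        if (d <= 0) stop("coincident cell centers");
        double a = (delta / sigma) * ::Rf_bessel_k(d / sigma, 1.0, 1.0) / d;
        fx += a * dx; fy += a * dy;
      }
      out(i, 0) = fx; out(i, 1) = fy;
    }
  }
  return out;
}

// undirected contact pairs (1-based, i < j) with inclusive threshold
// [[Rcpp::export]]
IntegerMatrix contact_pairs_cpp(NumericVector x, NumericVector y,
                                double threshold) {
  int n = x.size();
  Grid g;
  g.cell = threshold > 0 ? threshold : 1.0;
  for (int i = 0; i < n; ++i) g.insert(i, x[i], y[i]);
  double t2 = threshold * threshold * (1.0 + REL_EPS);
  std::vector<int> ei, ej;
  for (int i = 0; i < n; ++i) {
    int ix = g.bi(x[i]), iy = g.bi(y[i]);
    for (int ax = ix - 1; ax <= ix + 1; ++ax)
      for (int ay = iy - 1; ay <= iy + 1; ++ay) {
        auto it = g.bins.find(Grid::key(ax, ay));
        if (it == g.bins.end()) continue;
        for (int j : it->second) {
          if (j <= i) continue;
          double dx = x[j] - x[i], dy = y[j] - y[i];
          if (dx * dx + dy * dy <= t2) { ei.push_back(i + 1); ej.push_back(j + 1); }
        }
      }
  }
  IntegerMatrix out(ei.size(), 2);
  for (size_t k = 0; k < ei.size(); ++k) { out(k, 0) = ei[k]; out(k, 1) = ej[k]; }
  return out;
}

// ignore: 1-based index into (x, y) to skip, or 0 for none
// [[Rcpp::export]]
bool is_admissible_cpp(NumericVector x, NumericVector y, double cx, double cy,
                       double overlap_floor, int ignore) {
  double f2 = overlap_floor * overlap_floor;
  for (int j = 0; j < x.size(); ++j) {
    if (j + 1 == ignore) continue;
    double dx = x[j] - cx, dy = y[j] - cy;
    if (dx * dx + dy * dy < f2 * (1.0 - REL_EPS)) return false;
  }
  return true;
}
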