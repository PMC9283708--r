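#' Summary measures of one replicate run
#'
#' Network and population measures of the final configuration of a run,
#' as one data-frame row: total cells, network nodes, P_2, P_6, mean
#' degree, K_nn, transitivity, mean clustering, component counts and
#' sizes.  Replicates whose final network is empty (every cell isolated)
#' yield `NA` network measures.
#'
#' @param run a `tumor_run`.
#' @return One-row data frame.
#' @export
summarize_run <- function(run) {
  stopifnot(inherits(run, "tumor_run"))
  n_cells <- nrow(run$final$pos)
  net <- contact_network(run$final, run$params$contact_threshold)
  if (net$n_nodes == 0) {
    out <- data.frame(n_nodes = 0L, n_links = 0L, n_isolated = net$n_isolated,
                      p1 = NA_real_, p2 = NA_real_, p6 = NA_real_,
                      mean_degree = NA_real_, knn = NA_real_,
                      transitivity = NA_real_, mean_clustering = NA_real_,
                      n_components = NA_real_, s_max = NA_real_,
                      rho_c = NA_real_)
  } else {
    out <- as.data.frame(summary(net))
  }
  cbind(data.frame(n_cells = n_cells), out)
}

sweep_measures <- c("n_cells", "n_nodes", "p1", "p2", "p6", "mean_degree",
                    "knn", "transitivity", "mean_clustering",
                    "n_components", "s_max", "rho_c")

#' Sweep the attraction strength with surviving replicates
#'
#' For each attraction strength, collects `n_replicates` surviving runs
#' (via [run_surviving_replicates()]), summarizes the final configuration
#' of each and records the replicate mean and standard deviation of every
#' measure, indexed by the inverse attraction strength (the
#' temperature-like axis of the phase analysis).
#'
#' @param deltas positive attraction strengths to sweep.
#' @param base_params a [sim_params()]; `delta` and `seed` are overridden
#'   per grid point.
#' @param n_replicates surviving replicates per grid point (default 20).
#' @param seed_stride seed offset between grid points, at least the
#'   replicate attempt cap so seed ranges never overlap.
#' @return An object of class `sweep_curve`: long data frame with columns
#'   `delta`, `delta_inv`, `measure`, `mean`, `sd`, `n_reps`, ordered by
#'   increasing `delta_inv`.
#' @export
run_sweep <- function(deltas, base_params, n_replicates = 20,
                      seed_stride = 10 * n_replicates) {
  stopifnot(is.numeric(deltas), length(deltas) >= 1, all(deltas > 0),
            inherits(base_params, "sim_params"), n_replicates >= 1)
  deltas <- sort(deltas, decreasing = TRUE)   # increasing delta_inv
  rows <- vector("list", length(deltas))
  for (g in seq_along(deltas)) {
    p <- base_params
    p$delta <- deltas[g]
    p$seed <- base_params$seed + (g - 1L) * as.integer(seed_stride)
    runs <- run_surviving_replicates(p, n_replicates)
    stats <- do.call(rbind, lapply(runs, summarize_run))
    rows[[g]] <- do.call(rbind, lapply(sweep_measures, function(m) {
      v <- stats[[m]]
      data.frame(delta = deltas[g], delta_inv = 1 / deltas[g], measure = m,
                 mean = mean(v, na.rm = TRUE),
                 sd = if (sum(!is.na(v)) > 1) sd(v, na.rm = TRUE) else 0,
                 n_reps = sum(!is.na(v)))
    }))
  }
  structure(do.call(rbind, rows), class = c("sweep_curve", "data.frame"))
}

#' @export
print.sweep_curve <- function(x, ...) {
  cat(sprintf("Attraction-strength sweep: %d grid points, measures: %s\n",
              length(unique(x$delta)),
              paste(unique(x$measure), collapse = ", ")))
  NextMethod()
}

#' @export
plot.sweep_curve <- function(x, measure = "mean_degree", ...) {
  d <- x[x$measure == measure, , drop = FALSE]
  plot(d$delta_inv, d$mean, type = "b", pch = 19,
       xlab = expression(Delta^-1), ylab = measure, ...)
  graphics::arrows(d$delta_inv, d$mean - d$sd, d$delta_inv, d$mean + d$sd,
                   angle = 90, code = 3, length = 0.03)
  invisible(x)
}

#' Finite-difference derivative of a sampled curve
#'
#' Central differences at interior points, one-sided differences at the
#' ends.  An optional moving-average pre-smoothing (odd window; 1 = off)
#' tames replicate noise before differencing.
#'
#' @param x strictly increasing abscissae, length >= 3.
#' @param y ordinates.
#' @param smooth_window odd moving-average window applied to `y` first
#'   (default 1, i.e. identity).
#' @return Numeric vector `dy/dx` of the same length as `x`.
#' @export
finite_difference <- function(x, y, smooth_window = 1) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (any(diff(x) <= 0)) stop("x must be strictly increasing")
  stopifnot(smooth_window >= 1, smooth_window %% 2 == 1)
  if (smooth_window > 1) {
    h <- (smooth_window - 1) / 2
    y <- vapply(seq_along(y), function(i) {
      w <- max(1, i - h):min(length(y), i + h)
      mean(y[w])
    }, numeric(1))
  }
  n <- length(x)
  dy <- numeric(n)
  dy[1] <- (y[2] - y[1]) / (x[2] - x[1])
  dy[n] <- (y[n] - y[n - 1]) / (x[n] - x[n - 1])
  if (n > 2) {
    i <- 2:(n - 1)
    dy[i] <- (y[i + 1] - y[i - 1]) / (x[i + 1] - x[i - 1])
  }
  dy
}

#' Locate the transition peak of a derivative curve
#'
#' Finds the interior maximum of `dy` (or of `-dy` for decreasing
#' measures, whose transition shows as the most-negative derivative).  A
#' monotone curve with its extremum on the boundary yields a "no peak"
#' result rather than an error.  Ties break toward the lower abscissa.
#'
#' @param x strictly increasing abscissae.
#' @param dy derivative values.
#' @param search_range optional `c(lo, hi)` restriction on `x`.
#' @param decreasing set `TRUE` when the underlying measure decreases, so
#'   the peak is the extremum of the derivative's magnitude.
#' @return List with `found`, `location`, `uncertainty` (local grid
#'   spacing) and `value` (the derivative at the peak).
#' @export
locate_peak <- function(x, dy, search_range = range(x), decreasing = FALSE) {
  stopifnot(length(x) == length(dy), length(search_range) == 2)
  if (any(diff(x) <= 0)) stop("x must be strictly increasing")
  inr <- which(x >= search_range[1] & x <= search_range[2])
  if (length(inr) < 3) stop("fewer than 3 points in the search range")
  v <- dy[inr]
  if (decreasing) v <- -v
  k <- which.max(v)             # first maximum: lower-x tie-break
  if (k == 1 || k == length(inr))
    return(list(found = FALSE, location = NA_real_,
                uncertainty = NA_real_, value = NA_real_))
  i <- inr[k]
  list(found = TRUE, location = x[i],
       uncertainty = (x[i + 1] - x[i - 1]) / 2,
       value = dy[i])
}

#' Transition report constructor
#'
#' Holds the detected transition points on the inverse-attraction axis:
#' the solid-liquid point (peak of the P_6 derivative magnitude, also the
#' sharp mean-degree peak), the liquid-gas point (peak of the P_2
#' derivative, the wide mean-degree peak) and the rearrangement point
#' (transitivity-derivative peak, where degree 6 becomes the most probable
#' degree).  When all three are present they must be ordered
#' rearrangement < solid-liquid < liquid-gas.
#'
#' @param solid_liquid,liquid_gas,rearrangement peak locations on the
#'   inverse-attraction axis (`NA` when not detected).
#' @param uncertainties optional named numeric vector of +- uncertainties.
#' @return An object of class `transition_report`, with `phase_bounds`.
#' @export
transition_report <- function(solid_liquid, liquid_gas,
                              rearrangement = NA_real_,
                              uncertainties = NULL) {
  ok <- !is.na(c(rearrangement, solid_liquid, liquid_gas))
  pk <- c(rearrangement, solid_liquid, liquid_gas)
  if (sum(ok) >= 2 && any(diff(pk[ok]) <= 0))
    stop("transition points must be ordered rearrangement < solid-liquid < liquid-gas")
  structure(list(solid_liquid_peak = solid_liquid,
                 liquid_gas_peak = liquid_gas,
                 rearrangement_peak = rearrangement,
                 uncertainties = uncertainties,
                 phase_bounds = list(
                   solid = c(0, solid_liquid),
                   liquid = c(solid_liquid, liquid_gas),
                   gas = c(liquid_gas, Inf))),
            class = "transition_report")
}

#' @export
print.transition_report <- function(x, ...) {
  fmt <- function(v) if (is.na(v)) "not detected" else sprintf("%.4g", v)
  cat("Transition report (inverse attraction strength axis)\n")
  cat(sprintf("  rearrangement peak: %s\n", fmt(x$rearrangement_peak)))
  cat(sprintf("  solid-liquid peak:  %s\n", fmt(x$solid_liquid_peak)))
  cat(sprintf("  liquid-gas peak:    %s\n", fmt(x$liquid_gas_peak)))
  invisible(x)
}

#' Detect phase transitions from a sweep curve
#'
#' Differentiates the replicate-mean P_2, P_6 and transitivity curves
#' against the inverse attraction strength and locates their peaks: the
#' P_2 derivative peaks at the liquid-gas transition, the P_6 derivative
#' magnitude at the solid-liquid transition, and the transitivity
#' derivative magnitude at the rearrangement point inside the solid
#' phase.
#'
#' @param curve a [run_sweep()] result.
#' @param smooth_window moving-average window passed to
#'   [finite_difference()].
#' @return A [transition_report()].
#' @export
detect_transitions <- function(curve, smooth_window = 1) {
  stopifnot(inherits(curve, "sweep_curve"))
  peak_of <- function(measure, decreasing) {
    d <- curve[curve$measure == measure & is.finite(curve$mean), ,
               drop = FALSE]
    d <- d[order(d$delta_inv), , drop = FALSE]
    if (nrow(d) < 3) return(list(found = FALSE, location = NA_real_,
                                 uncertainty = NA_real_))
    dy <- finite_difference(d$delta_inv, d$mean, smooth_window)
    locate_peak(d$delta_inv, dy, decreasing = decreasing)
  }
  lg <- peak_of("p2", decreasing = FALSE)
  sl <- peak_of("p6", decreasing = TRUE)
  re <- peak_of("transitivity", decreasing = TRUE)
  transition_report(
    solid_liquid = sl$location, liquid_gas = lg$location,
    rearrangement = re$location,
    uncertainties = c(solid_liquid = sl$uncertainty,
                      liquid_gas = lg$uncertainty,
                      rearrangement = re$uncertainty))
}

#' Classify the tumor phase at a given inverse attraction strength
#'
#' Solid below the solid-liquid transition, gas above the liquid-gas
#' transition, liquid in between.
#'
#' @param delta_inv inverse attraction strength(s).
#' @param report a [transition_report()] with both main peaks detected.
#' @return Character vector: `"solid"`, `"liquid"` or `"gas"`.
#' @export
classify_phase <- function(delta_inv, report) {
  stopifnot(inherits(report, "transition_report"))
  if (is.na(report$solid_liquid_peak) || is.na(report$liquid_gas_peak))
    stop("phase classification requires both main transition peaks")
  ifelse(delta_inv < report$solid_liquid_peak, "solid",
         ifelse(delta_inv > report$liquid_gas_peak, "gas", "liquid"))
}

# ---------------------------------------------------------------------------
# synthetic configuration fixtures

#' Hexagonal (triangular-lattice) packing fixture
#'
#' Concentric shells of a triangular lattice at spacing exactly one cell
#' diameter, centered at the origin; shell counts 1, 7, 19, 37, ...  Every
#' interior node of the contact network has the maximum kissing degree 6,
#' which makes this the canonical solid-phase fixture.
#'
#' @param n_shells number of shells around the center cell (>= 0).
#' @return A [cell_config()].
#' @export
fixture_hexagonal <- function(n_shells) {
  stopifnot(n_shells >= 0)
  n <- as.integer(n_shells)
  qs <- -n:n
  pts <- do.call(rbind, lapply(qs, function(q) {
    rs <- max(-n, -q - n):min(n, -q + n)
    cbind(q + rs / 2, rs * sqrt(3) / 2)
  }))
  cell_config(pts[, 1], pts[, 2])
}

#' Hard-core gas fixture
#'
#' Rejection-sampled uniform points in a square box with all pairwise
#' distances at least `min_dist`; the gas-phase test fixture.
#'
#' @param n number of points.
#' @param box_side side of the square box.
#' @param min_dist hard-core distance (default 1).
#' @param seed RNG seed.
#' @param max_attempts total placement attempts before giving up.
#' @return A [cell_config()].
#' @export
fixture_hardcore_gas <- function(n, box_side, min_dist = 1.0, seed = 1,
                                 max_attempts = 1000 * n) {
  stopifnot(n >= 1, box_side > 0, min_dist >= 0)
  set.seed(seed)
  xs <- numeric(n); ys <- numeric(n)
  placed <- 0L; tries <- 0L
  while (placed < n) {
    if (tries >= max_attempts)
      stop("could not place the hard-core gas: density too high")
    tries <- tries + 1L
    cx <- runif(1, 0, box_side); cy <- runif(1, 0, box_side)
    if (placed == 0L ||
        min((xs[1:placed] - cx)^2 + (ys[1:placed] - cy)^2) >= min_dist^2) {
      placed <- placed + 1L
      xs[placed] <- cx; ys[placed] <- cy
    }
  }
  cell_config(xs, ys)
}

#' Clustered configuration fixture
#'
#' `k_clusters` compact hexagonal patches of `cluster_size` cells at
#' internal spacing `intra_spacing`, separated by gaps larger than the
#' contact threshold, so the contact network has exactly `k_clusters`
#' components; the liquid-phase / component-count fixture.
#'
#' @param k_clusters number of clusters.
#' @param cluster_size cells per cluster.
#' @param intra_spacing lattice spacing inside a cluster (<= 1 keeps a
#'   cluster connected).
#' @param inter_gap minimum gap between cluster envelopes (> contact
#'   threshold).
#' @param seed RNG seed (random rotation of each cluster).
#' @return A [cell_config()].
#' @export
fixture_clusters <- function(k_clusters, cluster_size, intra_spacing = 0.9,
                             inter_gap = 5, seed = 1) {
  stopifnot(k_clusters >= 1, cluster_size >= 1, intra_spacing > 0,
            inter_gap > 1)
  set.seed(seed)
  shells <- 0
  while (1 + 3 * shells * (shells + 1) < cluster_size) shells <- shells + 1
  patch <- fixture_hexagonal(shells)$pos * intra_spacing
  d2 <- patch[, 1]^2 + patch[, 2]^2
  patch <- patch[order(d2)[seq_len(cluster_size)], , drop = FALSE]
  span <- 2 * shells * intra_spacing + inter_gap + 2
  side <- ceiling(sqrt(k_clusters))
  pts <- do.call(rbind, lapply(seq_len(k_clusters) - 1L, function(k) {
    th <- runif(1, 0, 2 * pi)
    rot <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
    ctr <- c((k %% side) * span, (k %/% side) * span)
    sweep(patch %*% rot, 2, ctr, "+")
  }))
  cell_config(pts[, 1], pts[, 2])
}
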