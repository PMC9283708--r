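# Independent oracles used across the test files.  Everything here is
# deliberately implemented by a different route than the package code:
# Bessel functions via their integral representation, network measures via
# dense adjacency-matrix algebra, components via union-find, and the
# two-cell separation ODE via a fixed-step RK4 integrator.

# modified Bessel function of the second kind, integral representation
# K_nu(x) = int_0^inf exp(-x cosh t) cosh(nu t) dt
bessel_k_oracle <- function(x, nu = 0) {
  stats::integrate(function(t) exp(-x * cosh(t)) * cosh(nu * t),
                   0, 40, rel.tol = 1e-12)$value
}

# dense adjacency matrix of a configuration (inclusive threshold, with the
# same relative slack the package documents for exact-distance contacts)
oracle_adjacency <- function(pos, threshold = 1.0) {
  d <- as.matrix(stats::dist(pos))
  A <- (d <= threshold * (1 + 1e-9)) * 1
  diag(A) <- 0
  A
}

# drop isolated rows/cols (the network convention)
oracle_prune <- function(A) {
  keep <- rowSums(A) > 0
  A[keep, keep, drop = FALSE]
}

oracle_mean_degree <- function(A) mean(rowSums(A))

oracle_knn <- function(A) {
  k <- rowSums(A)
  mean(vapply(seq_len(nrow(A)), function(i) {
    nb <- which(A[i, ] > 0)
    mean(k[nb])
  }, numeric(1)))
}

# global clustering via the matrix-trace identity:
# T = trace(A^3) / sum_i k_i (k_i - 1)
oracle_transitivity <- function(A) {
  k <- rowSums(A)
  denom <- sum(k * (k - 1))
  if (denom == 0) return(0)
  sum(diag(A %*% A %*% A)) / denom
}

oracle_clustering <- function(A) {
  k <- rowSums(A)
  C <- vapply(seq_len(nrow(A)), function(i) {
    if (k[i] < 2) return(0)
    nb <- which(A[i, ] > 0)
    sum(A[nb, nb]) / (k[i] * (k[i] - 1))   # 2 L_i / (k (k-1))
  }, numeric(1))
  C
}

# connected components by union-find with path compression
oracle_components <- function(A) {
  n <- nrow(A)
  parent <- seq_len(n)
  find <- function(v) {
    while (parent[v] != v) {
      parent[v] <<- parent[parent[v]]
      v <- parent[v]
    }
    v
  }
  for (i in seq_len(n)) for (j in which(A[i, ] > 0)) {
    ri <- find(i); rj <- find(j)
    if (ri != rj) parent[ri] <- rj
  }
  roots <- vapply(seq_len(n), find, integer(1))
  as.integer(factor(roots))
}

# all-pairs brute-force net forces (attractive screened Bessel drift)
oracle_net_forces <- function(pos, delta, sigma) {
  n <- nrow(pos)
  out <- matrix(0, n, 2)
  if (delta == 0 || n < 2) return(out)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    rv <- pos[j, ] - pos[i, ]
    r <- sqrt(sum(rv^2))
    out[i, ] <- out[i, ] + (delta / sigma) * besselK(r / sigma, 1) * rv / r
  }
  out
}

# fixed-step RK4 for the noise-free two-cell separation,
# dr/dt = -2 (delta/sigma) K1(r/sigma); returns r at the requested times
oracle_separation_ode <- function(r0, delta, sigma, times, h = 1e-4) {
  f <- function(r) -2 * (delta / sigma) * besselK(r / sigma, 1)
  out <- numeric(length(times))
  r <- r0; t <- 0; k <- 1
  t_end <- max(times)
  while (k <= length(times)) {
    while (t < times[k] - 1e-12) {
      hh <- min(h, times[k] - t)
      k1 <- f(r)
      k2 <- f(r + hh / 2 * k1)
      k3 <- f(r + hh / 2 * k2)
      k4 <- f(r + hh * k3)
      r <- r + hh / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
      t <- t + hh
    }
    out[k] <- r
    k <- k + 1
  }
  out
}

# random configuration with a hard floor, small n, for oracle comparisons
random_admissible_config <- function(n, box, floor = 0.85, seed = 1) {
  fixture_hardcore_gas(n, box, min_dist = floor, seed = seed)
}
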