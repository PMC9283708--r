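#' Pair distribution function g(r)
#'
#' Histogram of inter-cell distances for one configuration:
#' `g(r) = (1/N) * sum over ordered pairs of 1[|r_ij| in bin] / bin width`.
#' This is the tumor convention, not the standard area-normalized 2-D
#' radial distribution function; with bins covering the full distance
#' range, the integrated mass is exactly `N - 1` (the N(N-1) ordered pairs
#' divided by N).  Ensemble averaging over replicates is left to the
#' caller.
#'
#' @param config a [cell_config()].
#' @param bin_edges strictly increasing numeric vector of bin edges
#'   (distances, in cell diameters).
#' @return An object of class `radial_histogram`: `bin_edges`, `mids`,
#'   `counts` (ordered-pair counts per bin), `density` (the g(r) values)
#'   and the recorded `normalization` convention.
#' @export
pair_distribution <- function(config, bin_edges) {
  stopifnot(inherits(config, "cell_config"),
            is.numeric(bin_edges), length(bin_edges) >= 2)
  if (any(diff(bin_edges) <= 0)) stop("bin_edges must be strictly increasing")
  n <- nrow(config$pos)
  nb <- length(bin_edges) - 1
  counts <- numeric(nb)
  if (n >= 2) {
    d <- as.numeric(stats::dist(config$pos))
    h <- graphics::hist(d[d >= bin_edges[1] & d < bin_edges[nb + 1]],
                        breaks = bin_edges, plot = FALSE, right = FALSE)
    counts <- 2 * h$counts          # ordered pairs
  }
  widths <- diff(bin_edges)
  structure(list(bin_edges = bin_edges,
                 mids = (head(bin_edges, -1) + tail(bin_edges, -1)) / 2,
                 counts = counts,
                 density = counts / (max(n, 1) * widths),
                 n_cells = n,
                 normalization = "ordered pairs / N / bin width"),
            class = "radial_histogram")
}

#' @export
print.radial_histogram <- function(x, ...) {
  cat(sprintf("Radial histogram: %d bins on [%g, %g], %d cells\n",
              length(x$counts), min(x$bin_edges), max(x$bin_edges),
              x$n_cells))
  cat(sprintf("  normalization: %s; total mass %.4f\n",
              x$normalization, sum(x$density * diff(x$bin_edges))))
  invisible(x)
}

#' @export
plot.radial_histogram <- function(x, log = "", ...) {
  plot(x$mids, x$density, type = "s", log = log,
       xlab = "r (cell diameters)", ylab = "g(r)", ...)
  invisible(x)
}

#' Radius of gyration
#'
#' Root-mean-square distance of the cells from their center of mass; the
#' characteristic linear size of the tumor.
#'
#' @param config a [cell_config()].
#' @return Scalar R_g (0 for a single cell).
#' @export
radius_of_gyration <- function(config) {
  stopifnot(inherits(config, "cell_config"))
  n <- nrow(config$pos)
  if (n == 0) stop("empty configuration")
  cm <- colMeans(config$pos)
  sqrt(mean((config$pos[, 1] - cm[1])^2 + (config$pos[, 2] - cm[2])^2))
}

#' Radius-of-gyration time series of a run
#'
#' Evaluates [radius_of_gyration()] on every stored snapshot of a
#' simulation run, in snapshot order.
#'
#' @param record a `tumor_run` (see [run_simulation()]) with snapshots.
#' @return Data frame with columns `time` and `rg`.
#' @export
gyration_series <- function(record) {
  stopifnot(inherits(record, "tumor_run"))
  if (length(record$snapshots) == 0) stop("run has no snapshots")
  data.frame(
    time = vapply(record$snapshots, function(s) s$time, numeric(1)),
    rg = vapply(record$snapshots, radius_of_gyration, numeric(1)))
}

#' Logarithmically binned histogram of component sizes
#'
#' Bins the pooled component sizes into factor-`base` logarithmic bins
#' `[base^k, base^(k+1))` and reports both raw counts and the bin-width
#' normalized density.  Slopes of power-law size distributions must be
#' fitted on the density: raw counts in factor-2 bins of an `s^-2` law
#' scale as `s^-1`.
#'
#' @param sizes integer vector of component sizes (pooled over replicates).
#' @param base logarithmic bin factor (default 2).
#' @return Data frame with columns `size` (geometric bin center), `lo`,
#'   `hi`, `count` and `density`.
#' @export
component_size_histogram <- function(sizes, base = 2) {
  stopifnot(length(sizes) >= 1, all(sizes >= 1), base > 1)
  k_max <- ceiling(log(max(sizes) + 1, base))
  edges <- base^(0:k_max)
  idx <- findInterval(sizes, edges)
  counts <- tabulate(idx, nbins = k_max)
  lo <- edges[-length(edges)]
  hi <- edges[-1]
  data.frame(size = sqrt(lo * hi), lo = lo, hi = hi, count = counts,
             density = counts / (hi - lo))
}

#' Fit a power-law slope on log-log axes
#'
#' Ordinary least squares of `log(y)` against `log(x)`, restricted to
#' `fit_range` and to strictly positive values.  Intended for
#' logarithmically binned histograms (use the density column) and for
#' g(r) tails.
#'
#' @param x abscissae (sizes or distances).
#' @param y ordinates (densities); zero bins are dropped.
#' @param fit_range optional `c(lo, hi)` restriction on `x`.
#' @return An object of class `power_law_fit` with `exponent`,
#'   `intercept`, `r_squared`, `fit_range` and `n_points`.
#' @export
fit_power_law_slope <- function(x, y, fit_range = NULL) {
  stopifnot(length(x) == length(y))
  keep <- is.finite(x) & is.finite(y) & x > 0 & y > 0
  if (!is.null(fit_range)) {
    stopifnot(length(fit_range) == 2, fit_range[1] < fit_range[2])
    keep <- keep & x >= fit_range[1] & x <= fit_range[2]
  }
  if (sum(keep) < 3)
    stop("fewer than 3 usable points for the power-law fit")
  lx <- log(x[keep]); ly <- log(y[keep])
  fit <- lm(ly ~ lx)
  ss_res <- sum(fit$residuals^2)
  ss_tot <- sum((ly - mean(ly))^2)
  structure(list(exponent = unname(coef(fit)[2]),
                 intercept = unname(coef(fit)[1]),
                 r_squared = if (ss_tot > 0) 1 - ss_res / ss_tot else 1,
                 fit_range = range(x[keep]),
                 n_points = sum(keep)),
            class = "power_law_fit")
}

#' @export
print.power_law_fit <- function(x, ...) {
  cat(sprintf(
    "Power-law fit: exponent %.4f (R^2 = %.4f, %d points on [%g, %g])\n",
    x$exponent, x$r_squared, x$n_points, x$fit_range[1], x$fit_range[2]))
  invisible(x)
}

#' Degree-colored snapshot table
#'
#' Merges cell positions with contact-network degrees for color-by-degree
#' plotting (the simulation's analogue of a stiffness image: stiff,
#' high-degree regions against loose, low-degree ones).  Isolated cells
#' carry degree 0.  Rows are ordered by cell id.
#'
#' @param config a [cell_config()].
#' @param net the matching [contact_network()]; built from `config` if
#'   omitted.
#' @return Data frame with columns `cell_id`, `x`, `y`, `degree`.
#' @export
degree_snapshot <- function(config, net = contact_network(config)) {
  stopifnot(inherits(config, "cell_config"),
            inherits(net, "contact_network"))
  degree <- integer(nrow(config$pos))
  degree[match(net$node_ids, config$ids)] <- net$degrees
  out <- data.frame(cell_id = config$ids, x = config$pos[, 1],
                    y = config$pos[, 2], degree = degree)
  out[order(out$cell_id), , drop = FALSE]
}
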