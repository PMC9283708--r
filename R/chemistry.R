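#' Force-field parameters for the screened chemical attraction
#'
#' The chemical field emitted by the cells obeys a screened Poisson
#' equation; in two dimensions a point source contributes K0(r / sigma) to
#' the field and the resulting pair force has magnitude
#' (delta / sigma) * K1(r / sigma), where K0 and K1 are modified Bessel
#' functions of the second kind.  `delta` is the dimensionless attraction
#' strength and `sigma` the dimensionless attraction (screening) range.
#'
#' K1 decays exponentially, so pair contributions beyond `cutoff` are
#' dropped; at the default `cutoff = 8 * sigma` the truncated force per
#' neighbor is bounded by (delta / sigma) * K1(8), about 2e-4 of its
#' value at contact.
#'
#' @param delta attraction strength, >= 0.
#' @param sigma attraction range, > 0 (default 1.5 cell diameters).
#' @param cutoff pair-interaction cutoff distance, >= sigma.
#' @return An object of class `force_field`.
#' @export
force_field <- function(delta, sigma = 1.5, cutoff = 8 * sigma) {
  stopifnot(is.numeric(delta), length(delta) == 1, is.finite(delta),
            delta >= 0,
            is.numeric(sigma), length(sigma) == 1, sigma > 0,
            is.numeric(cutoff), length(cutoff) == 1, cutoff >= sigma)
  structure(list(delta = delta, sigma = sigma, cutoff = cutoff),
            class = "force_field")
}

#' @export
print.force_field <- function(x, ...) {
  cat(sprintf(
    "Screened chemical attraction: delta = %g, sigma = %g, cutoff = %g\n",
    x$delta, x$sigma, x$cutoff))
  cat(sprintf("  dropped-pair force bound: %.3e\n",
              (x$delta / x$sigma) * besselK(x$cutoff / x$sigma, 1)))
  invisible(x)
}

#' Map physical cell parameters to the dimensionless simulation units
#'
#' The simulation runs entirely in dimensionless units: the cell diameter
#' `ell` is the unit of length and the proliferation cycle `tau` the unit of
#' time.  This record keeps the physical constants that were absorbed into
#' the two dimensionless control parameters: the attraction strength
#' Delta = mu * alpha0 * tau / ell^2 (with motility mu = kappa / nu) and the
#' attraction range sigma.  At the defaults the dimensionless cell
#' diffusion coefficient D * tau / ell^2 equals 1.
#'
#' @param tau cell proliferation cycle in seconds (default 1e4).
#' @param ell cell diameter in micrometers (default 10).
#' @param D_cell cell diffusion coefficient, um^2/s (default 1e-2).
#' @param D_chem chemical diffusion coefficient, um^2/s (default 1e2).
#' @param alpha0 chemical emission rate over the chemical diffusion
#'   coefficient.
#' @param lam chemical disappearance rate over the chemical diffusion
#'   coefficient.
#' @param kappa force strength.
#' @param nu friction coefficient.
#' @return An object of class `dimensional_mapping` with derived fields
#'   `mu` (motility), `delta` (dimensionless attraction strength) and
#'   `D_dimless` (dimensionless cell diffusion coefficient).
#' @export
dimensional_mapping <- function(tau = 1e4, ell = 10, D_cell = 1e-2,
                                D_chem = 1e2, alpha0 = 1, lam = 1,
                                kappa = 1, nu = 1) {
  stopifnot(tau > 0, ell > 0, D_cell > 0, D_chem > 0, nu > 0)
  mu <- kappa / nu
  structure(list(tau = tau, ell = ell, D_cell = D_cell, D_chem = D_chem,
                 alpha0 = alpha0, lam = lam, kappa = kappa, nu = nu,
                 mu = mu,
                 delta = mu * alpha0 * tau / ell^2,
                 D_dimless = D_cell * tau / ell^2),
            class = "dimensional_mapping")
}

#' @export
print.dimensional_mapping <- function(x, ...) {
  cat("Dimensional mapping (length unit = cell diameter, time unit = cycle)\n")
  cat(sprintf("  tau = %g s, ell = %g um, D_cell = %g um^2/s\n",
              x$tau, x$ell, x$D_cell))
  cat(sprintf("  motility mu = %g, attraction strength delta = %g\n",
              x$mu, x$delta))
  cat(sprintf("  dimensionless diffusion D = %g\n", x$D_dimless))
  invisible(x)
}

#' Pairwise attraction force between two cells
#'
#' Force exerted on cell i by cell j, for cells separated by
#' `r_vec = r_i - r_j` (the vector from j to i).  The magnitude is
#' (delta / sigma) * K1(|r_vec| / sigma) and the direction points from i
#' toward j: the chemical interaction is attractive, which is what drives
#' aggregation at large `delta`.  The force is antisymmetric under exchange
#' of the two cells.
#'
#' @param delta attraction strength.
#' @param sigma attraction range.
#' @param r_vec numeric 2-vector from cell j to cell i; must be nonzero
#'   (coincident centers are excluded by the overlap rule).
#' @return Numeric 2-vector, the force on cell i.
#' @export
pair_force <- function(delta, sigma, r_vec) {
  stopifnot(is.numeric(r_vec), length(r_vec) == 2, all(is.finite(r_vec)),
            delta >= 0, sigma > 0)
  r <- sqrt(sum(r_vec^2))
  if (r == 0) stop("zero separation: coincident cell centers")
  if (delta == 0) return(c(0, 0))
  -(delta / sigma) * besselK(r / sigma, 1) * r_vec / r
}

#' Net attraction force on every cell of a configuration
#'
#' Sum of [pair_force()] contributions over all interaction partners.  The
#' default `"grid"` method uses a cell-list neighbor search with the
#' force-field cutoff (the mode the simulation engine runs in); `"exact"`
#' sums over all pairs with no cutoff and direct Bessel evaluation, and is
#' retained as the testing oracle.  The two differ per cell by at most
#' N * (delta / sigma) * K1(cutoff / sigma).
#'
#' @param config a [cell_config()].
#' @param ff a [force_field()].
#' @param method `"grid"` or `"exact"`.
#' @return Numeric matrix with one row per cell and columns `fx`, `fy`,
#'   in the order of `config$ids`.
#' @export
net_forces <- function(config, ff, method = c("grid", "exact")) {
  method <- match.arg(method)
  stopifnot(inherits(config, "cell_config"), inherits(ff, "force_field"))
  out <- net_forces_cpp(config$pos[, 1], config$pos[, 2],
                        ff$delta, ff$sigma, ff$cutoff, method == "grid")
  dimnames(out) <- list(NULL, c("fx", "fy"))
  out
}

#' Stationary chemical field of a cell configuration
#'
#' Sum over sources of K0(|r - r_j| / sigma), in units where the emission
#' prefactor is one.  K0 diverges at the origin, so query points must not
#' coincide with source centers.
#'
#' @param sources a [cell_config()] of emitting cells.
#' @param query_points numeric matrix (or 2-vector) of query positions.
#' @param sigma attraction range.
#' @return Numeric vector, one field value per query point.
#' @export
chemical_field <- function(sources, query_points, sigma = 1.5) {
  stopifnot(inherits(sources, "cell_config"), sigma > 0)
  if (is.null(dim(query_points))) query_points <- matrix(query_points, ncol = 2)
  stopifnot(ncol(query_points) == 2, all(is.finite(query_points)))
  pos <- sources$pos
  if (nrow(pos) == 0) return(rep(0, nrow(query_points)))
  vapply(seq_len(nrow(query_points)), function(q) {
    d <- sqrt((pos[, 1] - query_points[q, 1])^2 +
              (pos[, 2] - query_points[q, 2])^2)
    if (any(d == 0)) stop("query point coincides with a source center")
    sum(besselK(d / sigma, 0))
  }, numeric(1))
}
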