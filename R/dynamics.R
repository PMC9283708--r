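#' Cell configuration
#'
#' The set of live cell-center positions at one time point, in units of the
#' cell diameter.  Stable integer ids identify cells across snapshots.
#'
#' @param x,y numeric vectors of cell-center coordinates.
#' @param ids integer cell identifiers, unique; default `seq_along(x)`.
#' @param time dimensionless time stamp of the snapshot.
#' @param check if `TRUE`, verify that all pairwise center distances are at
#'   least `overlap_floor`.
#' @param overlap_floor minimum admissible center distance used by the
#'   check (default 0.8: overlaps deeper than 0.2 cell diameters are
#'   rejected).
#' @return An object of class `cell_config` with elements `time`, `ids`
#'   and the n x 2 position matrix `pos`.
#' @export
cell_config <- function(x, y, ids = seq_along(x), time = 0,
                        check = FALSE, overlap_floor = 0.8) {
  stopifnot(is.numeric(x), is.numeric(y), length(x) == length(y),
            all(is.finite(x)), all(is.finite(y)),
            length(ids) == length(x), !anyDuplicated(ids),
            length(time) == 1, is.finite(time))
  ids <- as.integer(ids)
  cfg <- structure(list(time = time, ids = ids,
                        pos = cbind(x = as.numeric(x), y = as.numeric(y))),
                   class = "cell_config")
  if (check && length(x) > 1) {
    md <- min_pair_distance(cfg)
    if (md < overlap_floor * (1 - 1e-9))
      stop(sprintf("configuration violates the overlap floor: min distance %.4f < %.4f",
                   md, overlap_floor))
  }
  cfg
}

# smallest pairwise center distance (Inf for n < 2); cell-list based
min_pair_distance <- function(config) {
  n <- nrow(config$pos)
  if (n < 2) return(Inf)
  # widen the probe until at least one pair is seen
  probe <- 1
  repeat {
    pr <- contact_pairs_cpp(config$pos[, 1], config$pos[, 2], probe)
    if (nrow(pr) > 0 || probe > 1e6) break
    probe <- probe * 4
  }
  if (nrow(pr) == 0) return(Inf)
  d <- sqrt((config$pos[pr[, 1], 1] - config$pos[pr[, 2], 1])^2 +
            (config$pos[pr[, 1], 2] - config$pos[pr[, 2], 2])^2)
  min(d)
}

#' @export
print.cell_config <- function(x, ...) {
  cat(sprintf("Cell configuration: %d cells at time %g\n",
              nrow(x$pos), x$time))
  if (nrow(x$pos) > 0) {
    rg <- radius_of_gyration(x)
    cat(sprintf("  radius of gyration %.3f (cell diameters)\n", rg))
  }
  invisible(x)
}

#' @export
as.data.frame.cell_config <- function(x, ...) {
  data.frame(cell_id = x$ids, x = x$pos[, 1], y = x$pos[, 2])
}

#' @export
plot.cell_config <- function(x, ..., asp = 1, pch = 19, cex = 0.5) {
  plot(x$pos, asp = asp, pch = pch, cex = cex,
       xlab = "x (cell diameters)", ylab = "y (cell diameters)", ...)
  invisible(x)
}

#' Simulation parameters
#'
#' All dimensionless control parameters of one run.  The defaults are the
#' fixed values used throughout the phase analysis: diffusion D = 1, birth
#' rate 1 per cycle, death rate 0.1 per cycle, time step 0.001 and 40,000
#' steps; only the attraction strength `delta` is free.  Per-step event
#' probabilities `birth_rate * dt` and `death_rate * dt` must be valid
#' probabilities, and a growing tumor needs `birth_rate > death_rate`.
#'
#' @param delta attraction strength (>= 0).
#' @param sigma attraction range (default 1.5).
#' @param birth_rate division rate per unit time (default 1).
#' @param death_rate death rate per unit time (default 0.1).
#' @param diffusion dimensionless diffusion coefficient D (default 1;
#'   0 is allowed, giving noise-free drift dynamics for testing).
#' @param dt time step (default 0.001).
#' @param n_steps number of steps (default 40000).
#' @param seed RNG seed for the run.
#' @param max_retries placement attempts for rejected moves/births
#'   (default 100).
#' @param overlap_floor minimum admissible center distance (default 0.8,
#'   inclusive).
#' @param contact_threshold link distance of the contact network
#'   (default 1).
#' @param cutoff force cutoff (default `8 * sigma`).
#' @param snapshot_every record a configuration snapshot every this many
#'   steps (0 = final configuration only).
#' @return An object of class `sim_params`.
#' @export
sim_params <- function(delta, sigma = 1.5, birth_rate = 1, death_rate = 0.1,
                       diffusion = 1, dt = 0.001, n_steps = 40000L, seed = 1L,
                       max_retries = 100L, overlap_floor = 0.8,
                       contact_threshold = 1.0, cutoff = 8 * sigma,
                       snapshot_every = 0L) {
  stopifnot(is.numeric(delta), length(delta) == 1, is.finite(delta), delta >= 0,
            sigma > 0, cutoff >= sigma,
            birth_rate >= 0, death_rate >= 0,
            diffusion >= 0, dt > 0,
            birth_rate * dt <= 1, death_rate * dt <= 1,
            n_steps >= 0, max_retries >= 1,
            overlap_floor > 0, overlap_floor <= contact_threshold)
  if (birth_rate < death_rate)
    stop("birth_rate must be at least death_rate (the tumor cannot grow otherwise)")
  structure(list(delta = delta, sigma = sigma, birth_rate = birth_rate,
                 death_rate = death_rate, diffusion = diffusion, dt = dt,
                 n_steps = as.integer(n_steps), seed = as.integer(seed),
                 max_retries = as.integer(max_retries),
                 overlap_floor = overlap_floor,
                 contact_threshold = contact_threshold, cutoff = cutoff,
                 snapshot_every = as.integer(snapshot_every)),
            class = "sim_params")
}

#' @export
print.sim_params <- function(x, ...) {
  cat("Simulation parameters (dimensionless units)\n")
  cat(sprintf("  delta = %g, sigma = %g, cutoff = %g\n",
              x$delta, x$sigma, x$cutoff))
  cat(sprintf("  birth %g, death %g, D = %g, dt = %g, %d steps, seed %d\n",
              x$birth_rate, x$death_rate, x$diffusion, x$dt, x$n_steps,
              x$seed))
  cat(sprintf("  overlap floor %g, contact threshold %g, max retries %d\n",
              x$overlap_floor, x$contact_threshold, x$max_retries))
  invisible(x)
}

as_param_list <- function(params) {
  params[c("delta", "sigma", "cutoff", "birth_rate", "death_rate",
           "diffusion", "dt", "overlap_floor", "max_retries")]
}

config_from_cpp <- function(lst) {
  cell_config(lst$x, lst$y, ids = lst$id,
              time = if (is.null(lst$time) || is.na(lst$time)) 0 else lst$time)
}

# standalone sweeps operate in id order (the engine's iteration order)
sorted_config <- function(config) {
  o <- order(config$ids)
  list(x = config$pos[o, 1], y = config$pos[o, 2], id = config$ids[o])
}

#' Death sweep
#'
#' Each cell is removed independently with probability
#' `death_rate * dt`; survivors keep their positions and ids.  Uses the
#' current R RNG stream (seed with [set.seed()] for reproducibility).
#'
#' @param config a [cell_config()].
#' @param params a [sim_params()].
#' @return The surviving [cell_config()].
#' @export
death_sweep <- function(config, params) {
  s <- sorted_config(config)
  out <- death_sweep_cpp(s$x, s$y, s$id, as_param_list(params))
  out$time <- config$time
  config_from_cpp(out)
}

#' Birth sweep
#'
#' Each pre-existing cell divides independently with probability
#' `birth_rate * dt`.  The daughter is placed at distance exactly one cell
#' diameter at a uniform random angle; if the proposed site overlaps any
#' cell by more than the admissible depth (center distance below
#' `overlap_floor`), the angle is redrawn up to `max_retries` times, after
#' which the birth is rejected.  Daughters never divide within the sweep
#' that created them.
#'
#' @inheritParams death_sweep
#' @return The augmented [cell_config()]; daughters get fresh ids.
#' @export
birth_sweep <- function(config, params) {
  s <- sorted_config(config)
  out <- birth_sweep_cpp(s$x, s$y, s$id, as_param_list(params))
  out$time <- config$time
  config_from_cpp(out)
}

#' Move sweep (Euler-Maruyama step)
#'
#' Updates cells one by one in id order, each later cell seeing the
#' already-updated positions of earlier cells.  The proposed displacement
#' is `drift * dt + sqrt(2 * D * dt) * eta` with `eta` a standard Gaussian
#' 2-vector and the drift given by the net screened attraction
#' ([net_forces()]).  An inadmissible proposal redraws only the noise
#' vector, up to `max_retries` times, after which the cell stays where it
#' is.
#'
#' @inheritParams death_sweep
#' @return The moved [cell_config()].
#' @export
move_sweep <- function(config, params) {
  s <- sorted_config(config)
  out <- move_sweep_cpp(s$x, s$y, s$id, as_param_list(params))
  out$time <- config$time + params$dt
  config_from_cpp(out)
}

#' Is a candidate position admissible?
#'
#' A candidate center is admissible when it is at distance at least
#' `overlap_floor` (inclusive) from every other cell center: unit-diameter
#' cells are compressible, and overlap depth below 0.2 diameters is
#' accepted.
#'
#' @param config a [cell_config()] of existing cells.
#' @param candidate numeric 2-vector.
#' @param ignore_id id of a cell to exclude from the check (e.g. the moving
#'   cell itself), or `NULL`.
#' @param overlap_floor minimum admissible center distance.
#' @return Logical flag.
#' @export
is_admissible <- function(config, candidate, ignore_id = NULL,
                          overlap_floor = 0.8) {
  stopifnot(length(candidate) == 2, all(is.finite(candidate)))
  idx <- 0L
  if (!is.null(ignore_id)) {
    w <- which(config$ids == ignore_id)
    if (length(w) == 1) idx <- as.integer(w)
  }
  is_admissible_cpp(config$pos[, 1], config$pos[, 2],
                    candidate[1], candidate[2], overlap_floor, idx)
}

#' Run one tumor-growth simulation
#'
#' Starts from a single founder cell at the origin (or from `init`) and
#' advances `n_steps` steps.  Each step applies, in order, the death sweep,
#' the birth sweep and the move sweep.  The run terminates early, flagged
#' `extinct`, if the population reaches zero.  The whole trajectory is
#' reproducible from `params$seed`.
#'
#' @param params a [sim_params()].
#' @param init optional [cell_config()] to start from instead of the single
#'   founder at the origin.
#' @return An object of class `tumor_run`: list with `params`, `final`
#'   (a [cell_config()]), `extinct`, `population` (data frame of time and
#'   cell count per step) and `snapshots` (list of [cell_config()],
#'   recorded every `params$snapshot_every` steps, always including the
#'   final configuration).
#' @examples
#' p <- sim_params(delta = 1.5, n_steps = 200, seed = 42)
#' run <- run_simulation(p)
#' run
#' @export
run_simulation <- function(params, init = NULL) {
  stopifnot(inherits(params, "sim_params"))
  if (is.null(init)) {
    init <- cell_config(0, 0, ids = 1L, time = 0)
  } else {
    stopifnot(inherits(init, "cell_config"))
    md <- min_pair_distance(init)
    if (md < params$overlap_floor * (1 - 1e-9))
      stop("initial configuration violates the overlap floor")
  }
  s <- sorted_config(init)
  set.seed(params$seed)
  res <- run_simulation_cpp(s$x, s$y, s$id, init$time, as_param_list(params),
                            params$n_steps, params$snapshot_every)
  snaps <- lapply(res$snapshots, config_from_cpp)
  final <- config_from_cpp(res$final)
  snaps[[length(snaps) + 1]] <- final
  pop <- data.frame(
    time = init$time + params$dt * seq.int(0L, res$steps_done),
    n = res$population)
  structure(list(params = params, final = final,
                 extinct = isTRUE(res$extinct),
                 population = pop, snapshots = snaps),
            class = "tumor_run")
}

#' @export
print.tumor_run <- function(x, ...) {
  cat(sprintf("Tumor simulation: delta = %g, sigma = %g, seed = %d\n",
              x$params$delta, x$params$sigma, x$params$seed))
  cat(sprintf("  %d steps (t = %g), %s, final population %d\n",
              nrow(x$population) - 1, max(x$population$time),
              if (x$extinct) "EXTINCT" else "surviving",
              nrow(x$final$pos)))
  invisible(x)
}

#' @export
plot.tumor_run <- function(x, which = c("population", "cells"), ...) {
  which <- match.arg(which)
  if (which == "population") {
    plot(x$population$time, x$population$n, type = "l",
         xlab = "time (proliferation cycles)", ylab = "cells", ...)
  } else {
    plot(x$final, ...)
  }
  invisible(x)
}

#' @describeIn run_simulation one-row data frame of final-configuration
#'   measures (see [summarize_run()]).
#' @param object,... a `tumor_run` and further arguments (ignored).
#' @export
summary.tumor_run <- function(object, ...) {
  summarize_run(object)
}

#' Collect surviving replicate runs
#'
#' Launches runs with sequentially derived seeds (`params$seed + 0, 1, ...`)
#' until `n_survivors` non-extinct runs are collected.  Extinct runs are
#' counted and discarded, mirroring the convention that statistics are
#' taken over runs that still hold cells at the end.
#'
#' @param params a [sim_params()]; its `seed` is the base seed.
#' @param n_survivors number of surviving runs required.
#' @param max_attempts safety cap on total launches (default
#'   `10 * n_survivors`); exceeding it signals implausible parameters.
#' @return List of `n_survivors` surviving `tumor_run` objects, with the
#'   number of extinct runs attached as attribute `n_extinct`.
#' @export
run_surviving_replicates <- function(params, n_survivors,
                                     max_attempts = 10 * n_survivors) {
  stopifnot(inherits(params, "sim_params"), n_survivors >= 1)
  out <- vector("list", n_survivors)
  got <- 0L; tried <- 0L; extinct <- 0L
  while (got < n_survivors) {
    if (tried >= max_attempts)
      stop(sprintf(
        "replicate safety cap reached: %d attempts yielded %d survivors",
        tried, got))
    p <- params
    p$seed <- params$seed + tried
    tried <- tried + 1L
    run <- run_simulation(p)
    if (run$extinct) {
      extinct <- extinct + 1L
    } else {
      got <- got + 1L
      out[[got]] <- run
    }
  }
  attr(out, "n_extinct") <- extinct
  out
}
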