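base_params <- function(...) {
  sim_params(delta = 0, n_steps = 10L, seed = 1L, ...)
}

test_that("admissibility implements the 0.2-overlap compressibility rule", {
  empty <- cell_config(numeric(0), numeric(0), ids = integer(0))
  expect_true(is_admissible(empty, c(5, -3)))

  one <- cell_config(0, 0)
  expect_true(is_admissible(one, c(0.85, 0)))    # shallow overlap: fine
  expect_false(is_admissible(one, c(0.75, 0)))   # too deep
  expect_true(is_admissible(one, c(0.8, 0)))     # boundary is inclusive
  # the moving cell itself is excluded from its own check
  expect_true(is_admissible(one, c(0.1, 0), ignore_id = 1L))
})

test_that("death sweep removes cells at rate gamma * dt", {
  cfg <- fixture_hexagonal(2)

  p0 <- base_params(death_rate = 0)
  set.seed(42)
  expect_identical(death_sweep(cfg, p0)$pos, cfg$pos)

  p1 <- base_params(death_rate = 1000, dt = 0.001, birth_rate = 1000)
  set.seed(42)
  expect_identical(nrow(death_sweep(cfg, p1)$pos), 0L)

  # binomial law: 1e5 far-apart cells at gamma*dt = 1e-4
  n <- 1e5
  big <- cell_config(100 * (seq_len(n) %% 320), 100 * (seq_len(n) %/% 320))
  p <- base_params(death_rate = 0.1, dt = 0.001)
  set.seed(9)
  surv <- nrow(death_sweep(big, p)$pos) / n
  se <- sqrt(1e-4 * (1 - 1e-4) / n)
  expect_lt(abs(surv - (1 - 1e-4)), 3 * se)
})

test_that("birth sweep places daughters one diameter away or rejects them", {
  p <- base_params(birth_rate = 1000, dt = 0.001)  # certain division

  mother <- cell_config(2, 3)
  set.seed(1)
  out <- birth_sweep(mother, p)
  expect_identical(nrow(out$pos), 2L)
  d <- sqrt(sum((out$pos[2, ] - out$pos[1, ])^2))
  expect_equal(d, 1, tolerance = 1e-12)
  # the daughter gets a fresh id; the mother is untouched
  expect_identical(out$ids[1], 1L)
  expect_identical(out$pos[1, ], mother$pos[1, ])

  # zero birth probability: nothing happens
  p0 <- base_params(birth_rate = 0, death_rate = 0)
  set.seed(1)
  expect_identical(nrow(birth_sweep(mother, p0)$pos), 1L)

  # a mother kissed by 6 hexagonal neighbors can never place a daughter:
  # every angle leaves the daughter within 2 sin(15 deg) < 0.8 of a neighbor
  ring <- fixture_hexagonal(1)
  set.seed(5)
  for (rep in 1:20) {
    out <- birth_sweep(ring, p)
    # only ring cells (which have open outward space) may reproduce; the
    # center cell's birth is always rejected, so its daughter never appears
    # within distance 1 of the center with all-neighbor distances >= 0.8
    if (nrow(out$pos) > 7) {
      new <- out$pos[-(1:7), , drop = FALSE]
      d_center <- sqrt(new[, 1]^2 + new[, 2]^2)
      expect_true(all(d_center > 1 - 1e-9))
    }
  }

  # an isolated mother in certain-birth conditions: daughters never divide
  # within the sweep that created them (exactly one birth per sweep)
  set.seed(2)
  out <- birth_sweep(mother, p)
  expect_identical(nrow(out$pos), 2L)
})

test_that("every sweep preserves the overlap-floor invariant", {
  p <- sim_params(delta = 2, n_steps = 1L, seed = 1,
                  birth_rate = 100, death_rate = 10, dt = 0.001)
  cfg <- fixture_clusters(3, 7, intra_spacing = 0.95, seed = 8)
  set.seed(31)
  for (i in 1:30) {
    cfg <- death_sweep(cfg, p)
    cfg <- birth_sweep(cfg, p)
    cfg <- move_sweep(cfg, p)
    if (nrow(cfg$pos) < 2) break
    expect_gte(min_pair_distance(cfg), 0.8 * (1 - 1e-9))
  }
})

test_that("a free cell diffuses with mean squared displacement 4 D dt", {
  p <- base_params(diffusion = 1, dt = 0.001)
  one <- cell_config(0, 0)
  set.seed(77)
  n <- 1e4
  disp2 <- replicate(n, {
    moved <- move_sweep(one, p)
    sum((moved$pos[1, ] - one$pos[1, ])^2)
  })
  # |dr|^2 ~ 2Ddt * chisq(2): mean 4Ddt, sd 4Ddt
  expect_lt(abs(mean(disp2) - 4e-3), 3 * 4e-3 / sqrt(n))
})

test_that("noise-free two-cell drift follows the separation ODE", {
  # short-horizon version of the integrator check (the full t in [0,5]
  # comparison lives in the acceptance suite)
  delta <- 0.5; sigma <- 1.5; r0 <- 3
  p <- sim_params(delta = delta, sigma = sigma, diffusion = 0, dt = 1e-3,
                  n_steps = 1L, birth_rate = 0, death_rate = 0)
  cfg <- cell_config(c(-r0 / 2, r0 / 2), c(0, 0))
  set.seed(1)
  steps <- 1000
  for (s in seq_len(steps)) cfg <- move_sweep(cfg, p)
  r_sim <- sqrt(sum((cfg$pos[2, ] - cfg$pos[1, ])^2))
  r_ode <- oracle_separation_ode(r0, delta, sigma, times = 1)
  expect_lt(abs(r_sim - r_ode), 1e-3)
})

test_that("runs are reproducible and respect the stage order contract", {
  p <- sim_params(delta = 1.2, n_steps = 300, seed = 123,
                  snapshot_every = 100)
  r1 <- run_simulation(p)
  r2 <- run_simulation(p)
  expect_identical(r1$final$pos, r2$final$pos)
  expect_identical(r1$population, r2$population)
  expect_identical(lapply(r1$snapshots, `[[`, "pos"),
                   lapply(r2$snapshots, `[[`, "pos"))

  # every recorded snapshot satisfies the overlap floor
  for (s in r1$snapshots)
    expect_gte(min_pair_distance(s), 0.8 * (1 - 1e-9))

  # population series has one entry per step plus the start
  expect_identical(nrow(r1$population), 301L)
})

test_that("a lone founder with no birth or death diffuses freely", {
  p <- sim_params(delta = 0, birth_rate = 0, death_rate = 0,
                  n_steps = 200, seed = 1)
  nrep <- 400
  t_end <- 200 * p$dt
  msd <- mean(vapply(seq_len(nrep), function(k) {
    pk <- p; pk$seed <- k
    run <- run_simulation(pk)
    expect_identical(nrow(run$final$pos), 1L)
    sum(run$final$pos[1, ]^2)
  }, numeric(1)))
  se <- 4 * t_end / sqrt(nrep)     # sd of |dr|^2 equals its mean
  expect_lt(abs(msd - 4 * t_end), 3 * se)
})

test_that("certain death extinguishes the run and flags it", {
  p <- sim_params(delta = 1, birth_rate = 1000, death_rate = 1000,
                  dt = 0.001, n_steps = 10, seed = 2)
  run <- run_simulation(p)
  expect_true(run$extinct)
  expect_identical(nrow(run$final$pos), 0L)
})

test_that("sparse-gas births arrive at the binomial rate", {
  n <- 2000
  cfg <- cell_config(10 * (seq_len(n) %% 50), 10 * (seq_len(n) %/% 50))
  p <- sim_params(delta = 0, birth_rate = 10, death_rate = 0, dt = 0.01,
                  n_steps = 1, seed = 1)
  set.seed(12)
  births <- vapply(1:50, function(i) nrow(birth_sweep(cfg, p)$pos) - n,
                   numeric(1))
  pb <- 0.1
  se <- sqrt(n * pb * (1 - pb) / 50)
  expect_lt(abs(mean(births) - n * pb), 3 * se)
})

test_that("surviving-replicate collection replaces extinct runs", {
  # gamma = 0: every run survives, seeds are sequential and distinct
  p <- sim_params(delta = 0.5, birth_rate = 1, death_rate = 0,
                  n_steps = 50, seed = 10)
  runs <- run_surviving_replicates(p, 4)
  expect_length(runs, 4)
  expect_identical(vapply(runs, function(r) r$params$seed, integer(1)),
                   10L + 0:3)
  expect_identical(attr(runs, "n_extinct"), 0L)

  # certain extinction: the safety cap trips
  pdead <- sim_params(delta = 0.5, birth_rate = 1000, death_rate = 1000,
                      dt = 0.001, n_steps = 5, seed = 1)
  expect_error(run_surviving_replicates(pdead, 2), "safety cap")
})

test_that("parameter validation rejects inconsistent settings", {
  expect_error(sim_params(delta = -1), "delta")
  expect_error(sim_params(delta = 1, birth_rate = 0.05, death_rate = 0.1),
               "birth_rate")
  expect_error(sim_params(delta = 1, dt = 0.1, birth_rate = 20),
               "birth_rate")
  expect_error(sim_params(delta = 1, overlap_floor = 1.5,
                          contact_threshold = 1))
})
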