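test_that("finite differences reproduce simple calculus", {
  x <- c(0, 1, 2, 3)
  expect_equal(finite_difference(x, 2 * x + 1), rep(2, 4))
  # y = x^2: interior central differences are exact (2, 4)
  expect_equal(finite_difference(x, x^2)[2:3], c(2, 4))
  # window 1 is the identity smoother
  set.seed(1)
  y <- stats::rnorm(10)
  expect_equal(finite_difference(1:10, y, smooth_window = 1),
               finite_difference(1:10, y))
  expect_error(finite_difference(c(1, 1, 2), 1:3), "increasing")
  expect_error(finite_difference(1:2, 1:2))
})

test_that("peak location recovers synthetic transition points", {
  x <- seq(0.3, 1.0, by = 0.05)
  dy <- exp(-(x - 0.6)^2 / (2 * 0.01))   # Gaussian bump at 0.6
  pk <- locate_peak(x, dy)
  expect_true(pk$found)
  expect_equal(pk$location, 0.6, tolerance = 1e-12)
  expect_equal(pk$uncertainty, 0.05, tolerance = 1e-12)

  # symmetric double peak: tie breaks to the lower abscissa
  dy2 <- double(length(x))
  dy2[c(4, 10)] <- 1
  expect_equal(locate_peak(x, dy2)$location, x[4])

  # monotone derivative: no interior extremum, not an error
  expect_false(locate_peak(x, x^2)$found)

  # decreasing measures peak at the most negative derivative
  pk_dec <- locate_peak(x, -dy, decreasing = TRUE)
  expect_equal(pk_dec$location, 0.6)
  expect_equal(pk_dec$value, -1)

  expect_error(locate_peak(x[1:2], dy[1:2]), "3 points")
})

test_that("phase classification uses the two main transition peaks", {
  rep_ <- transition_report(solid_liquid = 0.476, liquid_gas = 0.66,
                            rearrangement = 0.417)
  expect_identical(classify_phase(0.3, rep_), "solid")
  expect_identical(classify_phase(0.55, rep_), "liquid")
  expect_identical(classify_phase(2.0, rep_), "gas")
  expect_identical(classify_phase(c(0.3, 0.55, 2), rep_),
                   c("solid", "liquid", "gas"))

  # the ordering invariant is enforced at construction
  expect_error(transition_report(solid_liquid = 0.7, liquid_gas = 0.66),
               "ordered")
  expect_error(classify_phase(0.5, transition_report(NA_real_, 0.66)),
               "both main")
})

test_that("hexagonal fixtures build exact triangular-lattice shells", {
  expect_identical(nrow(fixture_hexagonal(0)$pos), 1L)
  hex1 <- fixture_hexagonal(1)
  expect_identical(nrow(hex1$pos), 7L)
  expect_identical(max(contact_network(hex1)$degrees), 6L)
  hex2 <- fixture_hexagonal(2)
  expect_identical(nrow(hex2$pos), 19L)
  # all interior nodes (first shell and center) have degree 6
  net <- contact_network(hex2)
  r <- sqrt(rowSums(hex2$pos^2))
  interior <- which(r < 1.5)
  expect_identical(length(interior), 7L)
  expect_true(all(net$degrees[match(hex2$ids[interior], net$node_ids)] == 6L))
  # nearest-neighbor spacing is exactly 1
  expect_equal(min_pair_distance(hex2), 1, tolerance = 1e-12)
})

test_that("hard-core gas fixtures respect the floor and the seed", {
  expect_identical(nrow(fixture_hardcore_gas(1, 5, seed = 3)$pos), 1L)

  g <- fixture_hardcore_gas(40, 12, min_dist = 1.0, seed = 7)
  expect_gte(min_pair_distance(g), 1.0)
  g2 <- fixture_hardcore_gas(40, 12, min_dist = 1.0, seed = 7)
  expect_identical(g$pos, g2$pos)

  # spacing strictly above the threshold leaves every cell isolated
  sparse <- fixture_hardcore_gas(20, 30, min_dist = 1.05, seed = 1)
  net <- contact_network(sparse, threshold = 1.0)
  if (net$n_nodes == 0) {
    expect_identical(net$n_isolated, 20L)
  } else {
    # random placement may still land a pair within reach; the floor holds
    expect_gte(min_pair_distance(sparse), 1.05)
  }

  expect_error(fixture_hardcore_gas(200, 2, min_dist = 1, seed = 1,
                                    max_attempts = 500), "density")
})

test_that("clustered fixtures hold exactly k components", {
  cl <- fixture_clusters(3, 3, intra_spacing = 0.9, seed = 2)
  cc <- connected_components(contact_network(cl))
  expect_identical(cc$n_components, 3L)
  expect_identical(cc$sizes, c(3L, 3L, 3L))

  one <- fixture_clusters(1, 7, intra_spacing = 0.9, seed = 2)
  cc1 <- connected_components(contact_network(one))
  expect_identical(cc1$n_components, 1L)
  expect_identical(cc1$s_max, 7L)

  eq <- fixture_clusters(4, 5, intra_spacing = 0.9, seed = 3)
  cce <- connected_components(contact_network(eq))
  expect_identical(cce$s_max, 5L)
})

test_that("attraction sweeps aggregate replicate summaries", {
  p <- sim_params(delta = 1, n_steps = 100, seed = 5)
  curve <- run_sweep(1.5, p, n_replicates = 2)
  expect_s3_class(curve, "sweep_curve")
  expect_identical(unique(curve$delta_inv), 1 / 1.5)
  expect_true(all(is.finite(curve$mean[curve$measure == "n_cells"])))
  expect_true(all(curve$sd >= 0, na.rm = TRUE))
  # population measures always aggregate over the full replicate set;
  # network measures may drop replicates whose cells are all isolated
  expect_identical(curve$n_reps[curve$measure == "n_cells"], 2L)
  expect_true(all(curve$n_reps <= 2))

  # forcing identical replicate trajectories collapses the dispersion:
  # stride 0 reuses the same seed for every grid point / replicate pairing
  p1 <- sim_params(delta = 1, n_steps = 60, seed = 9, death_rate = 0)
  r1 <- run_simulation(p1)
  s1 <- summarize_run(r1)
  expect_identical(summarize_run(run_simulation(p1)), s1)  # determinism

  # two grid points: the measure-vs-delta_inv table is ordered and complete
  curve2 <- run_sweep(c(2.5, 0.8), p, n_replicates = 2)
  expect_identical(unique(curve2$delta), c(2.5, 0.8))
  expect_true(all(diff(curve2$delta_inv[curve2$measure == "p2"]) > 0))
  expect_identical(nrow(curve2), 2L * length(unique(curve2$measure)))
})

test_that("transition detection wires derivatives into the report", {
  # synthetic sweep curve with the shapes of the real measures: a rising
  # sigmoid for P2 (inflection 0.66), a falling sigmoid for P6
  # (inflection 0.476) and a falling transitivity (inflection 0.417)
  x <- seq(0.3, 1.0, by = 0.02)
  sig <- function(x0, w) 1 / (1 + exp(-(x - x0) / w))
  mk <- function(measure, mean) data.frame(delta = 1 / x, delta_inv = x,
                                           measure = measure, mean = mean,
                                           sd = 0, n_reps = 5)
  curve <- structure(rbind(mk("p2", 0.4 * sig(0.66, 0.03)),
                           mk("p6", 0.5 * (1 - sig(0.476, 0.02))),
                           mk("transitivity", 0.6 - 0.2 * sig(0.417, 0.015))),
                     class = c("sweep_curve", "data.frame"))
  rep_ <- detect_transitions(curve)
  expect_equal(rep_$liquid_gas_peak, 0.66, tolerance = 0.021)
  expect_equal(rep_$solid_liquid_peak, 0.476, tolerance = 0.021)
  expect_equal(rep_$rearrangement_peak, 0.417, tolerance = 0.021)
  expect_true(rep_$rearrangement_peak < rep_$solid_liquid_peak)
  expect_true(rep_$solid_liquid_peak < rep_$liquid_gas_peak)
})
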