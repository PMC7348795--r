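# Synthetic-data generator: walk moments, calibration, CT and count
# generation, determinism.

test_that("Rice moments agree with direct quadrature of the density", {
  for (par in list(c(0.5, 2), c(2, 1), c(5, 0.8), c(0, 3))) {
    nu <- par[1]; sigma <- par[2]
    expect_equal(rice_mean(nu, sigma), rice_mean_quadrature(nu, sigma),
                 tolerance = 1e-8)
  }
  # Rayleigh limit and deterministic limit
  expect_equal(rice_mean(0, 2), 2 * sqrt(pi / 2))
  expect_equal(rice_mean(4, 0), 4)
  expect_equal(rice_var(4, 0), 0)
})

test_that("degenerate walks give exact path lengths", {
  still <- walk_params(n_cells = 12, drift = 0, step_sd = 0, seed = 1)
  d0 <- simulate_cohort(still)
  expect_true(all(vapply(d0$trajectories, path_length, 1) == 0))
  drift <- walk_params(n_cells = 12, drift = 3, step_sd = 0, seed = 1)
  dd <- simulate_cohort(drift)
  expect_equal(vapply(dd$trajectories, path_length, 1), rep(36, 12))
})

test_that("driftless walks have the Rayleigh mean step length", {
  sigma <- 2.5
  wp <- walk_params(n_cells = 40, drift = 0, step_sd = sigma)
  pls <- unlist(lapply(1:50, function(r) {
    wp$seed <- 400 + r
    vapply(simulate_cohort(wp)$trajectories, path_length, 1)
  }))
  expected <- 12 * sigma * sqrt(pi / 2)
  se <- sd(pls) / sqrt(length(pls))
  expect_lt(abs(mean(pls) - expected), 3 * se)
})

test_that("calibration inverts the path-length moments", {
  # zero target SD: pure drift
  wp0 <- calibrate_walk(60, 0, n_steps = 12)
  expect_equal(wp0$drift, 5)
  expect_equal(wp0$step_sd, 0)
  # a feasible homogeneous target solves within the Rice family
  wp1 <- calibrate_walk(56.3, 6.64, n_steps = 12)
  expect_equal(wp1$drift_cv, 0)
  m <- rice_mean(wp1$drift, wp1$step_sd)
  v <- rice_var(wp1$drift, wp1$step_sd)
  expect_equal(12 * m, 56.3, tolerance = 1e-6)
  expect_equal(sqrt(12 * v), 6.64, tolerance = 1e-6)
  # over-dispersed targets exceed the homogeneous bound ...
  expect_error(calibrate_walk(74.7, 17.7, n_steps = 12,
                              heterogeneity = FALSE),
               "bound")
  # ... and are met exactly by the heterogeneous closed form
  wp2 <- calibrate_walk(74.7, 17.7, n_steps = 12)
  expect_gt(wp2$drift_cv, 0)
  m2 <- rice_mean(wp2$drift, wp2$step_sd)
  v2 <- rice_var(wp2$drift, wp2$step_sd)
  cv2 <- wp2$drift_cv^2
  expect_equal(12 * m2, 74.7, tolerance = 1e-6)
  expect_equal(12 * v2 * (1 + cv2) + 144 * m2^2 * cv2, 17.7^2,
               tolerance = 1e-6)
})

test_that("calibrated cohorts recover the target moments by simulation", {
  wp <- calibrate_walk(39.7, 8.96, n_cells = 15)
  pls <- unlist(lapply(1:200, function(r) {
    wp$seed <- 7000 + r
    vapply(simulate_cohort(wp)$trajectories, path_length, 1)
  }))
  expect_lt(abs(mean(pls) - 39.7) / 39.7, 0.02)
  expect_lt(abs(sd(pls) - 8.96) / 8.96, 0.10)
})

test_that("identical seeds give bit-identical cohorts", {
  wp <- calibrate_walk(74.7, 17.7, n_cells = 15, seed = 123)
  a <- simulate_cohort(wp, "V")
  b <- simulate_cohort(wp, "V")
  expect_identical(a, b)
  ct1 <- generate_ct_table(fold_targets(receptor_fold_targets(),
                                        ct_noise_sd = 0.2), seed = 5)
  ct2 <- generate_ct_table(fold_targets(receptor_fold_targets(),
                                        ct_noise_sd = 0.2), seed = 5)
  expect_identical(ct1, ct2)
  tc1 <- generate_transwell_counts(87.2, 25.8, 6, seed = 9)
  tc2 <- generate_transwell_counts(87.2, 25.8, 6, seed = 9)
  expect_identical(tc1, tc2)
})

test_that("gradient coupling biases motion up-gradient, monotonically in
           sensitivity", {
  prof <- solve_gll(params = transport_params(total_time = 6,
                                              grid_points = 60,
                                              output_times = c(0, 3, 6)))
  disp <- vapply(c(0.5, 2, 8), function(s) {
    wp <- walk_params(n_cells = 30, drift = 0, step_sd = 1, seed = 77,
                      start_window = c(0, 100),
                      gradient_coupling = list(profile = prof,
                                               sensitivity = s,
                                               channel_start_cm = 0.3))
    mean(vapply(simulate_cohort(wp)$trajectories,
                function(tr) tr$x[13] - tr$x[1], 1))
  }, 1)
  expect_true(all(disp > 0))
  expect_true(all(diff(disp) > 0))
})

test_that("CT tables realise fold targets, exactly or within noise", {
  targets <- fold_targets(receptor_fold_targets())
  ct <- generate_ct_table(targets)
  em <- expression_matrix(ct, rownames(targets$folds),
                          colnames(targets$folds))
  expect_equal(as.matrix(em), targets$folds, tolerance = 1e-12)
  # fold 1 everywhere: all ddCT are 0
  flat <- fold_targets(matrix(1, 2, 2, dimnames = list(c("s1", "s2"),
                                                       c("g1", "g2"))))
  ctf <- generate_ct_table(flat)
  for (s in c("s1", "s2")) for (g in c("g1", "g2"))
    expect_equal(delta_ct(ctf, s, g) - delta_ct(ctf, "control", g), 0)
  # noisy tables: mean recovered fold within 3 SE of target
  noisy <- fold_targets(receptor_fold_targets(), ct_noise_sd = 0.2)
  rec <- vapply(1:100, function(r) {
    tab <- generate_ct_table(noisy, seed = 800 + r)
    fold_change(tab, "VEGF", "control", "EGF-R")
  }, 1)
  se <- sd(rec) / sqrt(length(rec))
  # noise is symmetric in CT, hence slightly upward-biased in fold space;
  # compare against the lognormal-corrected expectation
  var_ddct <- 4 * 0.2^2 / 3
  expected <- 18.9 * 2^(var_ddct * log(2) / 2)
  expect_lt(abs(mean(rec) - expected), 3 * se)
})

test_that("transwell count generation rounds, truncates and converges", {
  exact <- generate_transwell_counts(87.2, 0, n_devices = 4, seed = 1)
  expect_true(all(exact$device_counts == 87))
  tiny <- generate_transwell_counts(0.4, 0, n_devices = 3, seed = 1)
  expect_true(all(tiny$device_counts == 0))
  big <- generate_transwell_counts(87.2, 25.8, n_devices = 4000, seed = 3)
  se <- 25.8 / sqrt(4000)
  expect_lt(abs(mean(big$device_counts) - 87.2), 3 * se)
  expect_true(all(big$device_counts >= 0))
  expect_error(generate_transwell_counts(-5, 1, 3), "positive")
})
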