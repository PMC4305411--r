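# Dual-pipette calibration: simulation, objective, model discrimination,
# redistribution-rate fitting.

test_that("pipette datasets validate their structure", {
  ts <- data.frame(time_min = c(5, 10, 30, 60), force_nN = c(50, 80, 200, 210))
  es <- data.frame(expression_pct = c(100, 58), force_nN_at_30min = c(200, 120))
  d <- pipette_dataset(ts, es)
  expect_s3_class(d, "pipette_dataset")
  expect_error(pipette_dataset(transform(ts, time_min = c(-5, 10, 30, 60)), es))
  expect_error(pipette_dataset(transform(ts, force_nN = -1), es))
})

test_that("the simulated two-cell force starts at zero and matures", {
  f <- simulate_pipette_force(kinetic_params(), "model2", 100, 60, dt = 0.02)
  expect_equal(f$force_nN[f$time == 0], 0)
  expect_true(all(diff(f$force_nN) > -1e-6))
  expect_equal(f$force_nN[f$time == 60], 210, tolerance = 0.15)
})

test_that("the 30-min force is non-decreasing in expression level", {
  levels <- c(100, 58, 41, 38, 14, 2)
  f30 <- vapply(levels, function(e) {
    f <- simulate_pipette_force(kinetic_params(), "model2", e, 30,
                                dt = 0.02, times = 30)
    f$force_nN[1]
  }, numeric(1))
  expect_true(all(diff(rev(f30)) >= 0))
})

test_that("the fitting objective is zero at the generating rates and
           invariant to data ordering", {
  dat <- synthetic_pipette_data(kinetic_params(), "model2", dt = 0.02)
  truth <- c(8.2, 0.6, 0.02, 0.6)
  expect_equal(pipette_objective(truth, dat, "model2", dt = 0.02), 0)
  shuffled <- pipette_dataset(dat$time_series,
                              dat$expression_series[c(4, 2, 6, 1, 3, 5), ])
  expect_equal(pipette_objective(truth * 1.3, dat, "model2", dt = 0.02),
               pipette_objective(truth * 1.3, shuffled, "model2", dt = 0.02))
  expect_equal(pipette_objective(c(-1, 1, 1, 1), dat, "model2"), 1e12)
  expect_error(fit_kinetics(dat, "model2", n_restarts = 0))
})

test_that("the static-adhesion variant cannot match dynamic-adhesion data", {
  # data generated by Model 2: its own objective is exactly zero, while
  # Model 1 saturates each site at expression/6 and overshoots the 210 nN
  # anchor (force ceiling 233 nN), so even a dedicated fit stays far off
  dat <- synthetic_pipette_data(kinetic_params(), "model2", dt = 0.02)
  set.seed(31)
  fit1 <- fit_kinetics(dat, "model1", n_restarts = 8, dt = 0.02,
                       maxit = 200, n_polish = 1, polish_maxit = 400)
  expect_gt(fit1$objective, 10)
  expect_equal(pipette_objective(c(8.2, 0.6, 0.02, 0.6), dat, "model2",
                                 dt = 0.02), 0)
})

test_that("three simultaneous cells split the bond budget in half", {
  sim <- three_cell_forces(kinetic_params(), "model2", staggered = FALSE,
                           horizon = 60, dt = 0.02)
  two <- simulate_pipette_force(kinetic_params(), "model2", 100, 60,
                                dt = 0.02, times = 60)
  last <- sim[nrow(sim), ]
  expect_equal(last$force_A_nN, two$force_nN[1] / 2, tolerance = 0.05)
  expect_equal(last$force_B_nN, two$force_nN[1] / 2, tolerance = 0.05)
  # symmetric up to the sequencing of pairwise position updates
  expect_equal(sim$force_A_nN, sim$force_B_nN, tolerance = 1e-3)
})

test_that("redistribution equalizes staggered contacts only when gamma > 0", {
  st <- three_cell_forces(kinetic_params(), "model2", staggered = TRUE,
                          horizon = 100, dt = 0.02)
  teq <- force_equalization_time(st)
  expect_false(is.na(teq))
  expect_lte(teq, 40)
  # without redistribution the second site starves (global cap already
  # filled by the first site) and the forces never meet
  st0 <- three_cell_forces(kinetic_params(gamma = 0), "model2",
                           staggered = TRUE, horizon = 100, dt = 0.02)
  expect_true(is.na(force_equalization_time(st0)))
})

test_that("the redistribution rate is recovered from self-generated timing", {
  truth <- 0.16
  st <- three_cell_forces(kinetic_params(gamma = truth), "model2",
                          staggered = TRUE, horizon = 100, dt = 0.02)
  target <- force_equalization_time(st) - 20   # delay after second contact
  fit <- fit_redistribution_rate(kinetic_params(), "model2",
                                 target_equalization = target, dt = 0.02)
  expect_equal(fit$gamma, truth, tolerance = 0.25)
})
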