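# Hertz repulsion, bond-to-force maps, force assembly, overdamped motion.

test_that("Hertz force matches its closed form and the potential derivative", {
  expect_equal(hertz_force(10, 5, 5), 0)
  expect_equal(hertz_force(12, 5, 5), 0)
  # printed correspondence: ~2.18e3 pN at 8.5 um, Table-1 parameters
  f85 <- hertz_force(8.5, 5, 5)
  expect_equal(f85, 1.5^1.5 * sqrt(2.5) / (0.75 * 2 * (1 - 1 / 9) / 1000),
               tolerance = 1e-12)
  expect_equal(f85, 2180, tolerance = 2e-3)
  # strictly increasing in overlap
  d <- seq(9.9, 5, length.out = 50)
  expect_true(all(diff(hertz_force(d, 5, 5)) > 0))
  # force = -dV/dd on random parameter tuples
  set.seed(5)
  for (k in 1:100) {
    Ri <- runif(1, 2, 8); Rj <- runif(1, 2, 8)
    si <- runif(1, 0, 0.49); sj <- runif(1, 0, 0.49)
    Ei <- runif(1, 100, 5000); Ej <- runif(1, 100, 5000)
    d0 <- runif(1, 0.3 * (Ri + Rj), 0.98 * (Ri + Rj))
    f <- hertz_force(d0, Ri, Rj, si, sj, Ei, Ej)
    fd <- -num_deriv(function(x) hertz_potential(x, Ri, Rj, si, sj, Ei, Ej), d0)
    expect_equal(f, fd, tolerance = 1e-6)
  }
})

test_that("bond-to-force maps hit the dual-pipette anchors", {
  expect_equal(adhesion_force("model2", 80, 80), 210000)
  expect_equal(adhesion_force("model1", 15, 15), 210000)
  expect_equal(adhesion_force("model2", 0, 50), 0)
  # the poorer side limits the bond count
  expect_equal(adhesion_force("model2", 40, 80), 105000)
  # linear, uncapped extrapolation
  expect_equal(adhesion_force("model1", 16.5, 16.5), 16.5 / 15 * 210000)
  # Model 3 separation-force rule: nothing at or inside the natural state
  expect_equal(adhesion_force("model3", 80, 80, d = 8), 0)
  expect_equal(adhesion_force("model3", 80, 80, d = 8.51), 0)
  expect_equal(adhesion_force("model3", 80, 80, d = 9), 210000)
  expect_error(adhesion_force("model9", 1, 1))
  expect_error(adhesion_force("model3", 1, 1))  # needs a distance
})

test_that("hexagon assembly gives zero net force and the 13 000 pN pressure", {
  w <- make_hexagon_world(spacing = 8.5)
  fp <- net_force_and_pressure(1, w, "model2", mech_params())
  expect_equal(fp$force, c(0, 0), tolerance = 1e-9)
  expect_equal(fp$pressure, 6 * hertz_force(8.5, 5, 5), tolerance = 1e-9)
  expect_equal(fp$pressure, 13000, tolerance = 0.01)
  # isolated cell
  w1 <- build_world(data.frame(x = 0, y = 0))
  fp1 <- net_force_and_pressure(1, w1, "model2")
  expect_equal(fp1$force, c(0, 0))
  expect_equal(fp1$pressure, 0)
})

test_that("pair forces obey Newton's third law", {
  w <- build_world(data.frame(x = c(0, 8.7), y = c(0, 1.5)))
  w$contacts$EBc_i <- 3; w$contacts$EBc_j <- 5
  for (v in c("model1", "model2", "model3")) {
    f1 <- net_force_and_pressure(1, w, v)$force
    f2 <- net_force_and_pressure(2, w, v)$force
    expect_equal(f1, -f2, tolerance = 1e-9)
  }
})

test_that("Stokes drag converts force to velocity at the printed scale", {
  expect_equal(stokes_drag(5, 10), 6 * pi * 10 / 60 * 5, tolerance = 1e-12)
  # 942.5 pN on an R = 5 cell -> 1 um/s = 60 um/min
  expect_equal(942.5 / stokes_drag(5, 10), 60, tolerance = 1e-3)
})

test_that("motion is overdamped, monotone and respects the variant semantics", {
  # zero force, zero noise: nothing moves
  w <- build_world(data.frame(x = c(0, 30), y = c(0, 0)))
  w2 <- motion_step(w, 1, "model2")
  expect_equal(w2$cells$x, w$cells$x)

  # pure repulsion: an overlapping pair separates monotonically to h = 0
  w <- build_world(data.frame(x = c(0, 8), y = c(0, 0)))
  d_prev <- 8
  for (k in 1:40) {
    w <- motion_step(w, 0.2, "model2")
    d_now <- abs(diff(w$cells$x))
    expect_gte(d_now + 1e-12, d_prev)
    d_prev <- d_now
  }
  expect_equal(d_prev, 10, tolerance = 1e-2)

  # Model 2 with a fixed bond level relaxes to the adhesion/repulsion balance
  m <- 4  # percent bound; balance where Hertz == m/80 * 210 nN
  d_bal <- uniroot(function(d) hertz_force(d, 5, 5) - m / 80 * 210000,
                   c(0.5, 10 - 1e-6))$root
  w <- build_world(data.frame(x = c(0, 9.5), y = c(0, 0)))
  w$contacts$EBc_i <- m; w$contacts$EBc_j <- m
  for (k in 1:80) {
    w$contacts$prev_area <- w$contacts$area  # freeze bookkeeping effects
    w <- motion_step(w, 0.1, "model2")
  }
  expect_equal(abs(diff(w$cells$x)), d_bal, tolerance = 1e-2)

  # Model 3: same bond level only resists separation, so the pair relaxes
  # into [natural state, R_i + R_j] - strictly beyond the Model 2 distance
  w <- build_world(data.frame(x = c(0, 9.5), y = c(0, 0)))
  w$contacts$EBc_i <- m; w$contacts$EBc_j <- m
  for (k in 1:80) w <- motion_step(w, 0.1, "model3")
  d3 <- abs(diff(w$cells$x))
  expect_gte(d3, natural_state_distance(5))
  expect_lte(d3, 10)
  expect_gt(d3, d_bal)
})

test_that("random forces are zero-mean about the deterministic drift", {
  set.seed(6)
  mech <- mech_params(noise_amp = 40)
  disp <- t(replicate(400, {
    w <- build_world(data.frame(x = 0, y = 0))
    w <- motion_step(w, 0.5, "model2", mech)
    c(w$cells$x, w$cells$y)
  }))
  se <- apply(disp, 2, sd) / sqrt(nrow(disp))
  expect_true(all(abs(colMeans(disp)) < 4 * se + 1e-12))
})
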