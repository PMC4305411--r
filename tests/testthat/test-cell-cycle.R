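# Cycle state machine, pressure arrest, oriented division.

test_that("generation times are uniform on 17-27 h with mean 22 h", {
  set.seed(7)
  cyc <- cycle_params()
  rest <- draw_rest_duration(cyc, 2000)
  gen <- (cyc$t_G1 + cyc$t_M + rest) / 60
  expect_true(all(gen >= 17 & gen <= 27))
  expect_equal(mean(gen), 22, tolerance = 0.02)
})

test_that("G1 grows the radius linearly and hands over to REST", {
  cyc <- cycle_params()
  cell <- new_cell(1, 0, 0, radius = 5 / 2^(1 / 3), phase = "G1")
  out <- advance_cycle(cell, cyc$t_G1 / 2, pressure = 0, cycle = cyc)
  R_div <- 5 / 2^(1 / 3)
  expect_equal(out$cell$radius, R_div + (5 - R_div) / 2, tolerance = 1e-9)
  expect_equal(out$cell$phase, "G1")
  out <- advance_cycle(out$cell, cyc$t_G1 / 2, pressure = 0, cycle = cyc)
  expect_equal(out$cell$phase, "REST")
  expect_equal(out$cell$radius, 5)
  expect_false(out$divide)
})

test_that("the pressure gate blocks mitosis and releases when unloaded", {
  cyc <- cycle_params()
  cell <- new_cell(1, 0, 0, phase = "REST")
  cell$rest_duration <- 600
  cell$phase_clock <- 599
  # below threshold: division fires at the boundary
  out <- advance_cycle(cell, 2, pressure = 12000, cycle = cyc,
                       contact_inhibition = TRUE)
  expect_true(out$divide)
  # above threshold with inhibition on: held, flagged arrested
  out <- advance_cycle(cell, 2, pressure = 14000, cycle = cyc,
                       contact_inhibition = TRUE)
  expect_false(out$divide)
  expect_true(out$cell$arrested)
  # re-checked every step: pressure drop releases the arrest
  out2 <- advance_cycle(out$cell, 1, pressure = 100, cycle = cyc,
                        contact_inhibition = TRUE)
  expect_true(out2$divide)
  expect_false(out2$cell$arrested)
  # inhibition disabled: pressure is ignored
  out <- advance_cycle(cell, 2, pressure = 1e6, cycle = cyc,
                       contact_inhibition = FALSE)
  expect_true(out$divide)
})

test_that("division conserves volume and splits along the compression axis", {
  daughters <- divide_cell(new_cell(1, 2, 3), c(1, 0), ids = c(10L, 11L))
  r_d <- daughters[[1]]$radius
  expect_equal(r_d, 5 / 2^(1 / 3), tolerance = 1e-12)
  expect_equal(2 * r_d^3, 5^3, tolerance = 1e-12)   # exact volume conservation
  expect_equal(daughters[[1]]$x - daughters[[2]]$x, 5)
  expect_equal(daughters[[1]]$sibling, 11L)
  expect_equal(daughters[[2]]$sibling, 10L)
  expect_equal(daughters[[1]]$phase, "M")

  # single compressed neighbour along +x: the axis is +-x
  ax <- division_axis(rep_forces = 2000, directions = matrix(c(1, 0), 1))
  expect_equal(abs(ax), c(1, 0), tolerance = 1e-9)
  # two equal orthogonal compressions: isotropic, axis drawn at random
  set.seed(8)
  ax <- division_axis(c(1000, 1000), matrix(c(1, 0, 0, 1), 2, byrow = TRUE))
  expect_equal(sum(ax^2), 1, tolerance = 1e-9)
})

test_that("daughters inherit a conservation-consistent pathway state", {
  cell <- new_cell(1, 0, 0, E = 20, B = 20, EB = 30,
                   sites = data.frame(partner = 2L, area = 10,
                                      prev_area = 10, EBc = 50))
  daughters <- divide_cell(cell, c(0, 1), ids = c(2L, 3L))
  for (d in daughters) {
    expect_equal(d$E + d$EB + sum(d$sites$EBc), 100)   # expression level
    expect_equal(d$B + d$EB + sum(d$sites$EBc), 100)
    expect_equal(nrow(d$sites), 0)
  }
})

test_that("an unconstrained engine population divides on the cycle clock", {
  # two generations from one cell: by 29 h every cell has divided at least
  # once (max generation 27 h) and none more than twice (min 2 x 17 h)
  traj <- colony_run("model3", 0.6, ci = FALSE, days = 29 / 24, seed = 11)
  expect_equal(traj$status, "done")
  n_final <- traj$metrics$n_cells[nrow(traj$metrics)]
  expect_gte(n_final, 2)
  expect_lte(n_final, 4)
})
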