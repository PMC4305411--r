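# Compartmentalized E-cadherin/beta-catenin kinetics.

test_that("area change factors are normalized relative gains and losses", {
  expect_equal(unlist(area_change_factors(10, 10)), c(a_c = 0, a_d = 0))
  expect_equal(unlist(area_change_factors(0, 10)), c(a_c = 0, a_d = 1))
  expect_equal(unlist(area_change_factors(10, 8)), c(a_c = 0.2, a_d = 0))
  expect_equal(area_change_factors(5, 0)$a_c, 1)  # de novo site
  # both bounded in [0, 1] over random pairs
  set.seed(1)
  a <- area_change_factors(runif(100, 0, 50), runif(100, 0, 50))
  expect_true(all(a$a_c >= 0 & a$a_c <= 1 & a$a_d >= 0 & a$a_d <= 1))
})

test_that("exocytosis combines directed and undirected transport under saturation", {
  p <- kinetic_params()
  # arithmetic oracle for the undirected term: rho_u * EB * A / (4 pi r^2)
  flux <- exocytosis_flux(EB = 50, area = 21.53, radius = 5, a_c = 0,
                          EBc_site = 0, EBc_total = 0, expression = 100,
                          variant = "model2", params = p)
  expect_equal(flux, 8.2 * 50 * 21.53 / (4 * pi * 25), tolerance = 1e-12)
  expect_equal(flux, 28.1, tolerance = 1e-2)
  # nothing to transport
  expect_equal(exocytosis_flux(0, 10, 5, 1, 0, 0, 100, "model2", p), 0)
  # Model 1: site saturates at tau_E = expression / 6
  expect_equal(exocytosis_flux(50, 10, 5, 1, 100 / 6, 100 / 6, 100,
                               "model1", p), 0)
  # Model 2: global cap at 0.8 * expression
  expect_equal(exocytosis_flux(50, 10, 5, 1, 10, 80, 100, "model2", p), 0)
  # directed term responds to the area gain
  f0 <- exocytosis_flux(50, 10, 5, 0, 0, 0, 100, "model2", p)
  f1 <- exocytosis_flux(50, 10, 5, 0.5, 0, 0, 100, "model2", p)
  expect_equal(f1 - f0, p$rho_c * 50 * 0.5, tolerance = 1e-12)
})

test_that("redistribution follows the positive-bracket rule and conserves", {
  r <- redistribution_fluxes(c(30, 10, 20), 0.16)
  # the poorest site receives from both richer sites
  expect_equal(r$r_in[2], 0.16 * ((30 - 10) + (20 - 10)))
  expect_equal(r$r_out[2], 0)
  expect_equal(r$r_out[1], 0.16 * ((30 - 10) + (30 - 20)))
  expect_equal(sum(r$r_in), sum(r$r_out))
  # symmetry and degenerate cases
  expect_equal(unlist(redistribution_fluxes(c(7, 7, 7), 0.16)),
               rep(0, 6), ignore_attr = TRUE)
  expect_equal(nrow(redistribution_fluxes(numeric(0), 0.16)), 0)
  expect_equal(unlist(redistribution_fluxes(42, 0.16)),
               c(r_in = 0, r_out = 0))
  # conservation over random site vectors
  set.seed(2)
  for (k in 1:20) {
    r <- redistribution_fluxes(runif(sample(2:8, 1), 0, 80), 0.16)
    expect_equal(sum(r$r_in - r$r_out), 0, tolerance = 1e-12)
  }
})

test_that("pathway derivatives are mass-action and conserve both species", {
  p <- kinetic_params(rho_d = 0.5)
  # detached site: d_i = rho_d * a_d * EBc flows back to the cytosol pool
  cell <- new_cell(1, 0, 0, E = 30, B = 30, EB = 30,
                   sites = data.frame(partner = 2L, area = 0,
                                      prev_area = 10, EBc = 40))
  rhs <- pathway_rhs(cell, "model2", p)
  expect_equal(rhs$dEBc, -0.5 * 1 * 40)
  expect_equal(rhs$dEB, p$nu_p * 30 * 30 - p$nu_n * 30 + 20)
  # conservation by construction, random states, both variants
  set.seed(3)
  for (variant in c("model1", "model2")) {
    for (k in 1:20) {
      ns <- sample(0:4, 1)
      sites <- data.frame(partner = seq_len(ns), area = runif(ns, 0, 30),
                          prev_area = runif(ns, 0, 30),
                          EBc = runif(ns, 0, 10))
      cell <- new_cell(1, 0, 0, E = 20, B = 15, EB = 5, sites = sites)
      rhs <- pathway_rhs(cell, variant, p)
      expect_equal(rhs$dE + rhs$dEB + sum(rhs$dEBc), 0, tolerance = 1e-12)
      expect_equal(rhs$dB + rhs$dEB + sum(rhs$dEBc), 0, tolerance = 1e-12)
    }
  }
  expect_error(pathway_rhs(new_cell(1, 0, 0, E = -1), "model2", p))
})

test_that("isolated cell relaxes to the closed-form binding equilibrium", {
  cell <- new_cell(1, 0, 0)
  for (k in 1:6000) cell <- step_pathway(cell, 0.05, "model2", kinetic_params())
  expect_equal(cell$EB, steady_state_EB(), tolerance = 1e-6)
  expect_equal(cell$EB, 58.2, tolerance = 1e-3)
  expect_equal(cell$E, 100 - steady_state_EB(), tolerance = 1e-6)
  # the rhs vanishes there
  rhs <- pathway_rhs(cell, "model2", kinetic_params())
  expect_lt(abs(rhs$dEB), 1e-5)
})

test_that("stepping preserves conservation, positivity and the variant caps", {
  set.seed(4)
  p <- kinetic_params(rho_d = 2)
  for (variant in c("model1", "model2")) {
    cell <- new_cell(1, 0, 0, sites = data.frame(
      partner = 1:3, area = c(20, 5, 0.5), prev_area = c(18, 6, 0.1),
      EBc = c(0, 0, 0)))
    for (k in 1:4000) {
      # jitter the areas so both gain and loss terms fire; areas stay
      # within the geometric bound pi R^2
      cell$sites$prev_area <- cell$sites$area
      cell$sites$area <- pmin(pi * 25,
                              pmax(0, cell$sites$area * runif(3, 0.9, 1.12)))
      cell <- step_pathway(cell, 0.025, variant, p)
      if (k %% 500 == 0) {
        tot <- cell$EB + sum(cell$sites$EBc)
        expect_equal(cell$E + tot, 100, tolerance = 1e-6)
        expect_equal(cell$B + tot, 100, tolerance = 1e-6)
        expect_true(all(c(cell$E, cell$B, cell$EB, cell$sites$EBc) >= 0))
        if (variant == "model1") {
          expect_true(all(cell$sites$EBc <= 100 / 6 + 1e-6))
        } else {
          expect_lte(sum(cell$sites$EBc), 80 + 1e-6)
        }
      }
    }
  }
})

test_that("redistribution equalizes two fixed-area sites and conserves mass", {
  cell <- new_cell(1, 0, 0, E = 10, B = 10, EB = 10,
                   sites = data.frame(partner = 1:2, area = c(10, 10),
                                      prev_area = c(10, 10), EBc = c(80, 0)))
  total0 <- cell$EB + sum(cell$sites$EBc)
  for (k in 1:4000) cell <- step_pathway(cell, 0.02, "model2",
                                         kinetic_params(rho_u = 0, nu_p = 0,
                                                        nu_n = 0, rho_c = 0))
  expect_equal(cell$sites$EBc[1], cell$sites$EBc[2], tolerance = 1e-6)
  expect_equal(cell$EB + sum(cell$sites$EBc), total0, tolerance = 1e-9)
})

test_that("halving the step changes the two-cell trajectory by < 1%", {
  f1 <- simulate_pipette_force(kinetic_params(), "model2", 100, 30,
                               dt = 0.02, times = c(10, 30))
  f2 <- simulate_pipette_force(kinetic_params(), "model2", 100, 30,
                               dt = 0.01, times = c(10, 30))
  expect_equal(f1$force_nN, f2$force_nN, tolerance = 0.01)
})
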