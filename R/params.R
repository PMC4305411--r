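#' Mechanical parameters of a cell
#'
#' Bundles the biophysical constants used by the contact mechanics and the
#' equation of motion. Defaults are the values used throughout the colony
#' simulations: maximum radius 5 um, Poisson ratio 1/3, elastic modulus
#' 1 kPa, medium viscosity 10^2 Poise (10 Pa s), and a contact-inhibition
#' pressure threshold of 13 000 pN (the summed Hertz repulsion on a cell
#' with six neighbours at ~8.5 um spacing).
#'
#' Note on units: 1 Pa equals 1 pN/um^2, so `E_mod` in Pa can be combined
#' directly with lengths in um to give forces in pN.
#'
#' @param R maximum cell radius, um.
#' @param sigma Poisson ratio, dimensionless, in `[0, 0.5)`.
#' @param E_mod elastic modulus, Pa.
#' @param eta viscosity of the suspension medium, Pa s.
#' @param noise_amp amplitude (standard deviation per component) of the
#'   zero-mean random force, pN. Default 0 (noise off).
#' @param pressure_threshold contact-inhibition pressure threshold, pN.
#' @return An object of class `mech_params` (a named list).
#' @examples
#' mech_params()
#' mech_params(noise_amp = 50)
#' @export
mech_params <- function(R = 5, sigma = 1 / 3, E_mod = 1000, eta = 10,
                        noise_amp = 0, pressure_threshold = 13000) {
  stopifnot(R > 0, sigma >= 0, sigma < 0.5, E_mod > 0, eta > 0,
            noise_amp >= 0, pressure_threshold >= 0)
  structure(list(R = R, sigma = sigma, E_mod = E_mod, eta = eta,
                 noise_amp = noise_amp,
                 pressure_threshold = pressure_threshold),
            class = "mech_params")
}

#' Kinetic rate constants of the adhesion pathway
#'
#' Rates of the compartmentalized E-cadherin/beta-catenin model, all per
#' minute. Defaults are the values fitted against the dual-pipette
#' separation-force data: `rho_u = 8.2` (undirected complex translocation),
#' `nu_n = 0.6` (complex dissociation), `nu_p = 0.02` (complex binding, per
#' percent per minute), `rho_c = 0.6` (directed translocation) and
#' `gamma = 0.16` (inter-site redistribution, Models 2/3 only).
#'
#' `rho_d`, the endocytosis rate of complexes freed by junction disassembly,
#' is scenario-dependent; the colony sweeps vary it over several orders of
#' magnitude, with 0.6 the value that best reproduces epithelial
#' neighbour-number statistics. It defaults to 0.6 here.
#'
#' @param nu_p complex binding rate, per percent per minute.
#' @param nu_n complex dissociation rate, per minute.
#' @param rho_c directed translocation (exocytosis) rate, per minute.
#' @param rho_u undirected translocation rate, per minute.
#' @param rho_d endocytosis rate after junction disassembly, per minute.
#' @param gamma inter-site redistribution rate, per minute.
#' @return An object of class `kinetic_params` (a named list).
#' @examples
#' kinetic_params()
#' kinetic_params(rho_d = 500)
#' @export
kinetic_params <- function(nu_p = 0.02, nu_n = 0.6, rho_c = 0.6,
                           rho_u = 8.2, rho_d = 0.6, gamma = 0.16) {
  rates <- c(nu_p = nu_p, nu_n = nu_n, rho_c = rho_c, rho_u = rho_u,
             rho_d = rho_d, gamma = gamma)
  if (any(!is.finite(rates)) || any(rates < 0)) {
    stop("all kinetic rates must be finite and non-negative")
  }
  structure(as.list(rates), class = "kinetic_params")
}

#' Cell-cycle parameters
#'
#' The cycle consists of a fixed-length G1 growth phase (7 h), a combined
#' G0/S/G2 resting phase of uniformly distributed length (8-18 h) and a
#' fixed-length M phase (2 h) during which the two daughters form a
#' dumb-bell with mutually suppressed interactions. Total generation time is
#' therefore uniform on 17-27 h, mean 22 h. At the rest-to-M transition a
#' cell whose pressure exceeds `MechParams$pressure_threshold` holds in the
#' resting phase (contact inhibition) until the pressure drops.
#'
#' @param t_G1 length of the G1 growth phase, min.
#' @param t_M length of the M phase, min.
#' @param rest_min,rest_max bounds of the uniform rest-phase duration, min.
#' @return An object of class `cycle_params` (a named list).
#' @examples
#' cycle_params()
#' @export
cycle_params <- function(t_G1 = 7 * 60, t_M = 2 * 60,
                         rest_min = 8 * 60, rest_max = 18 * 60) {
  stopifnot(t_G1 > 0, t_M > 0, rest_min > 0, rest_max >= rest_min)
  structure(list(t_G1 = t_G1, t_M = t_M,
                 rest_min = rest_min, rest_max = rest_max),
            class = "cycle_params")
}

#' @export
print.mech_params <- function(x, ...) {
  cat("Cell mechanics: R =", x$R, "um, sigma =", signif(x$sigma, 4),
      ", E =", x$E_mod, "Pa, eta =", x$eta, "Pa s\n")
  cat("  noise amplitude:", x$noise_amp, "pN;  pressure threshold:",
      x$pressure_threshold, "pN\n")
  invisible(x)
}

#' @export
print.kinetic_params <- function(x, ...) {
  cat("Adhesion pathway rates (per min):\n")
  cat(sprintf("  nu_p = %g  nu_n = %g  rho_c = %g  rho_u = %g  rho_d = %g  gamma = %g\n",
              x$nu_p, x$nu_n, x$rho_c, x$rho_u, x$rho_d, x$gamma))
  invisible(x)
}

#' @export
print.cycle_params <- function(x, ...) {
  cat(sprintf("Cell cycle: G1 %g h + rest U(%g, %g) h + M %g h\n",
              x$t_G1 / 60, x$rest_min / 60, x$rest_max / 60, x$t_M / 60))
  invisible(x)
}

# internal: coerce user input (plain list allowed) to a validated params object
as_mech_params <- function(x) {
  if (inherits(x, "mech_params")) return(x)
  do.call(mech_params, modifyList(formals_defaults(mech_params), as.list(x)))
}
as_kinetic_params <- function(x) {
  if (inherits(x, "kinetic_params")) return(x)
  do.call(kinetic_params, modifyList(formals_defaults(kinetic_params), as.list(x)))
}
as_cycle_params <- function(x) {
  if (inherits(x, "cycle_params")) return(x)
  do.call(cycle_params, modifyList(formals_defaults(cycle_params), as.list(x)))
}

formals_defaults <- function(f) {
  d <- formals(f)
  lapply(d, eval, envir = baseenv())
}

# model variants ------------------------------------------------------------

#' Model variant identifiers
#'
#' `variant_names()` lists the three supported model variants. Variant
#' `"model1"` is the static adhesion hypothesis (per-site complex cap of one
#' sixth of the cell's E-cadherin content, force anchor 15% <-> 210 nN),
#' `"model2"` the dynamic adhesion hypothesis (global cap of 80% with
#' inter-site redistribution, anchor 80% <-> 210 nN) and `"model3"` Model 2
#' kinetics with the separation-force rule (no attraction at or inside the
#' natural-state distance).
#'
#' @return Character vector of valid variant names.
#' @examples
#' variant_names()
#' @export
variant_names <- function() c("model1", "model2", "model3")

check_variant <- function(variant) {
  variant <- match.arg(tolower(variant), variant_names())
  variant
}

# Reference separation force (pN) and the bound-complex level (%) at which it
# is attained, per variant. 210 nN is the dual-pipette anchor.
FORCE_REF_PN <- 210000
anchor_pct <- function(variant) {
  switch(variant, model1 = 15, model2 = 80, model3 = 80)
}
# Fraction of a cell's E-cadherin content that can be contact-bound in
# Models 2/3 (global saturation), and per-site cap divisor for Model 1.
MODEL2_SAT_FRACTION <- 0.8
MODEL1_SITE_DIVISOR <- 6
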