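# Compartmentalized E-cadherin / beta-catenin pathway.
#
# Species, all in % of the maximum number of complexes a cell can form
# (100 = every E-cadherin or beta-catenin molecule in a complex):
#   E    free E-cadherin (cytosol)
#   B    free beta-catenin (cytosol)
#   EB   complexes in the cytosol or at non-contact membrane sites
#   EBc_i complexes in the compartment of contact site i
# Conservation (no production or degradation):
#   E + EB + sum(EBc) = expression,  B + EB + sum(EBc) = 100.

#' Construct a cell state
#'
#' A cell for the R-level pathway and mechanics operations: position,
#' radius, pathway species and a table of contact sites. Initial conditions
#' follow the standard set-up: free E-cadherin at the expression level, free
#' beta-catenin at 100%, no complexes.
#'
#' @param id integer cell identifier.
#' @param x,y position in the monolayer plane, um.
#' @param radius cell radius, um.
#' @param expression E-cadherin expression level, % (total E-cadherin).
#' @param E,B,EB initial species levels, %.
#' @param sites data.frame with columns `partner`, `area`, `prev_area`,
#'   `EBc` (one row per contact site), or `NULL` for an isolated cell.
#' @param phase one of `"G1"`, `"REST"`, `"M"`.
#' @return A list of class `colony_cell`.
#' @examples
#' new_cell(1, 0, 0)
#' @export
new_cell <- function(id = 1L, x = 0, y = 0, radius = 5, expression = 100,
                     E = expression, B = 100, EB = 0, sites = NULL,
                     phase = "REST") {
  if (is.null(sites)) {
    sites <- data.frame(partner = integer(), area = numeric(),
                        prev_area = numeric(), EBc = numeric())
  }
  cell <- list(id = as.integer(id), x = x, y = y, radius = radius,
               expression = expression, E = E, B = B, EB = EB,
               sites = sites, phase = phase, phase_clock = 0,
               rest_duration = NA_real_, arrested = FALSE,
               sibling = NA_integer_)
  class(cell) <- "colony_cell"
  check_cell(cell)
  cell
}

check_cell <- function(cell, tol = 1e-6) {
  conc <- c(cell$E, cell$B, cell$EB, cell$sites$EBc)
  if (any(conc < -tol)) stop("negative pathway concentration")
  invisible(cell)
}

#' Relative contact-area change factors
#'
#' For one contact site, the relative gain `a_c` and loss `a_d` of contact
#' area since the previous bookkeeping step:
#' `a_c = max(0, (area - prev_area) / max(area, eps))` and
#' `a_d = max(0, (prev_area - area) / max(prev_area, eps))`, both clamped to
#' `[0, 1]`. A site that fully detaches (`area = 0`, `prev_area > 0`) has
#' `a_d = 1`, which drives endocytosis of the orphaned complexes at rate
#' `rho_d`. A site that appears de novo has `a_c = 1`.
#'
#' @param area current contact area, um^2 (vectorized).
#' @param prev_area contact area at the previous bookkeeping step, um^2.
#' @param eps guard against division by zero.
#' @return A data.frame with columns `a_c` and `a_d`, both dimensionless.
#' @examples
#' area_change_factors(10, 8)   # a_c = 0.2
#' area_change_factors(0, 10)   # a_d = 1 (complete disassembly)
#' @export
area_change_factors <- function(area, prev_area, eps = 1e-12) {
  stopifnot(all(area >= 0), all(prev_area >= 0))
  a_c <- pmax(0, (area - prev_area) / pmax(area, eps))
  a_d <- pmax(0, (prev_area - area) / pmax(prev_area, eps))
  data.frame(a_c = pmin(a_c, 1), a_d = pmin(a_d, 1))
}

#' Exocytosis flux into one contact site
#'
#' Transport of cytosolic complexes to a contact site combines directed
#' exocytosis (rate `rho_c`, driven by the relative area gain `a_c`) and
#' undirected transport (rate `rho_u`, proportional to the ratio of the
#' contact area to the cell surface area `4 pi r^2`). Both components share
#' a saturation factor that encodes the variant's capacity bound:
#' Model 1 caps each site at `tau_E = expression / 6`; Models 2/3 cap the
#' total over all sites at `0.8 * expression`.
#'
#' @param EB cytosolic complex level, %.
#' @param area contact area of the site, um^2.
#' @param radius cell radius, um.
#' @param a_c relative contact-area gain (see [area_change_factors()]).
#' @param EBc_site bound complexes already at this site, %.
#' @param EBc_total bound complexes summed over all of the cell's sites, %.
#' @param expression total E-cadherin of the cell, %.
#' @param variant `"model1"`, `"model2"` or `"model3"`.
#' @param params [kinetic_params()].
#' @return Flux in % per minute (non-negative scalar).
#' @examples
#' p <- kinetic_params()
#' exocytosis_flux(50, 21.53, 5, 0, 0, 0, 100, "model2", p)
#' @export
exocytosis_flux <- function(EB, area, radius, a_c, EBc_site, EBc_total,
                            expression, variant, params) {
  variant <- check_variant(variant)
  stopifnot(EB >= 0, area >= 0, radius > 0)
  sat <- if (variant == "model1") {
    tau_E <- expression / MODEL1_SITE_DIVISOR
    max(0, 1 - EBc_site / tau_E)
  } else {
    max(0, 1 - EBc_total / (MODEL2_SAT_FRACTION * expression))
  }
  surface <- 4 * pi * radius^2
  (params$rho_c * a_c + params$rho_u * area / surface) * EB * sat
}

#' Inter-site redistribution fluxes (Models 2/3)
#'
#' Complexes flow between a cell's contact sites from richer to poorer
#' sites: site `i` receives `gamma * sum_j max(0, EBc_j - EBc_i)` and loses
#' `gamma * sum_j max(0, EBc_i - EBc_j)` (sums over the cell's other sites,
#' only positive brackets contribute). Redistribution conserves the total:
#' `sum(r_in) == sum(r_out)`.
#'
#' @param EBc numeric vector of bound-complex levels per site, %.
#' @param gamma redistribution rate, per minute.
#' @return A data.frame with columns `r_in` and `r_out`, % per minute.
#' @examples
#' redistribution_fluxes(c(30, 10, 20), 0.16)
#' @export
redistribution_fluxes <- function(EBc, gamma) {
  stopifnot(gamma >= 0, all(EBc >= 0))
  n <- length(EBc)
  if (n <= 1) {
    return(data.frame(r_in = numeric(n), r_out = numeric(n)))
  }
  diff <- outer(EBc, EBc, "-")           # diff[i, j] = EBc_i - EBc_j
  r_out <- gamma * rowSums(pmax(diff, 0))
  r_in <- gamma * colSums(pmax(diff, 0))
  data.frame(r_in = r_in, r_out = r_out)
}

#' Time derivatives of the pathway species of one cell
#'
#' Mass-action right-hand side of the compartment model:
#' \deqn{dE/dt = dB/dt = -\nu_p E B + \nu_n EB}
#' \deqn{dEB/dt = \nu_p E B - \nu_n EB - \sum_i c_i + \sum_i d_i}
#' \deqn{dEBc_i/dt = c_i - d_i (+ r^{in}_i - r^{out}_i \;\mathrm{Models\ 2/3})}
#' with exocytosis `c_i` from [exocytosis_flux()], endocytosis after
#' junction disassembly `d_i = rho_d * a_d_i * EBc_i` and redistribution
#' from [redistribution_fluxes()]. The derivatives sum to zero over all
#' E-containing species (and over all beta-catenin-containing species), so
#' conservation holds by construction.
#'
#' @param cell a [new_cell()] state.
#' @param variant model variant name.
#' @param params [kinetic_params()].
#' @return List with elements `dE`, `dB`, `dEB` (scalars) and `dEBc`
#'   (vector, one entry per contact site).
#' @examples
#' pathway_rhs(new_cell(1, 0, 0), "model2", kinetic_params())
#' @export
pathway_rhs <- function(cell, variant, params) {
  variant <- check_variant(variant)
  check_cell(cell)
  bind <- params$nu_p * cell$E * cell$B
  diss <- params$nu_n * cell$EB
  s <- cell$sites
  n <- nrow(s)
  if (n == 0) {
    return(list(dE = -bind + diss, dB = -bind + diss,
                dEB = bind - diss, dEBc = numeric(0)))
  }
  ac <- area_change_factors(s$area, s$prev_area)
  total <- sum(s$EBc)
  c_i <- vapply(seq_len(n), function(i) {
    exocytosis_flux(cell$EB, s$area[i], cell$radius, ac$a_c[i],
                    s$EBc[i], total, cell$expression, variant, params)
  }, numeric(1))
  d_i <- params$rho_d * ac$a_d * s$EBc
  dEBc <- c_i - d_i
  if (variant %in% c("model2", "model3")) {
    r <- redistribution_fluxes(s$EBc, params$gamma)
    dEBc <- dEBc + r$r_in - r$r_out
  }
  list(dE = -bind + diss, dB = -bind + diss,
       dEB = bind - diss - sum(c_i) + sum(d_i),
       dEBc = dEBc)
}

#' Advance the pathway of one cell by one time step
#'
#' Forward-Euler update of all pathway species with exact-conservation flux
#' limiting: within a (sub)step, the outflows of any pool are scaled down so
#' the pool cannot undershoot zero, and inter-site transfers are scaled
#' pairwise so redistribution stays conservative. The step is internally
#' subdivided whenever any pool would lose more than half its content in a
#' single substep. With the default engine step of 0.01 min the trajectory
#' is converged to well under 1% (halving `dt` is a no-op at that level).
#'
#' @param cell a [new_cell()] state.
#' @param dt time step, min.
#' @param variant model variant name.
#' @param params [kinetic_params()].
#' @return The updated cell.
#' @examples
#' step_pathway(new_cell(1, 0, 0), 0.01, "model2", kinetic_params())
#' @export
step_pathway <- function(cell, dt, variant, params) {
  variant <- check_variant(variant)
  stopifnot(dt > 0)
  check_cell(cell)
  n_sub <- pathway_substeps(cell, dt, variant, params)
  h <- dt / n_sub
  for (k in seq_len(n_sub)) {
    cell <- pathway_euler_substep(cell, h, variant, params)
  }
  cell
}

# number of substeps so no pool loses more than half its content per substep
pathway_substeps <- function(cell, dt, variant, params, max_sub = 16L) {
  n_sub <- 1L
  repeat {
    h <- dt / n_sub
    out <- pathway_outflow_fractions(cell, h, variant, params)
    if (all(out <= 0.5) || n_sub >= max_sub) return(n_sub)
    n_sub <- n_sub * 2L
  }
}

pathway_outflow_fractions <- function(cell, h, variant, params) {
  rhs <- pathway_rhs(cell, variant, params)
  bind <- params$nu_p * cell$E * cell$B
  diss <- params$nu_n * cell$EB
  s <- cell$sites
  ac <- area_change_factors(s$area, s$prev_area)
  total <- sum(s$EBc)
  c_i <- if (nrow(s)) vapply(seq_len(nrow(s)), function(i) {
    exocytosis_flux(cell$EB, s$area[i], cell$radius, ac$a_c[i],
                    s$EBc[i], total, cell$expression, variant, params)
  }, numeric(1)) else numeric(0)
  d_i <- params$rho_d * ac$a_d * s$EBc
  r_out <- if (variant != "model1" && nrow(s) > 1) {
    redistribution_fluxes(s$EBc, params$gamma)$r_out
  } else rep(0, nrow(s))
  frac <- c(
    if (cell$E > 0) bind * h / cell$E else 0,
    if (cell$B > 0) bind * h / cell$B else 0,
    if (cell$EB > 0) (diss + sum(c_i)) * h / cell$EB else 0,
    ifelse(s$EBc > 0, (d_i + r_out) * h / pmax(s$EBc, 1e-300), 0)
  )
  frac
}

pathway_euler_substep <- function(cell, h, variant, params) {
  s <- cell$sites
  n <- nrow(s)
  bind <- params$nu_p * cell$E * cell$B
  diss <- params$nu_n * cell$EB
  # limit binding against both reactant pools
  if (bind > 0) {
    lim <- min(1, cell$E / (bind * h), cell$B / (bind * h))
    bind <- bind * lim
  }
  ac <- if (n) area_change_factors(s$area, s$prev_area) else NULL
  total <- if (n) sum(s$EBc) else 0
  c_i <- if (n) vapply(seq_len(n), function(i) {
    exocytosis_flux(cell$EB, s$area[i], cell$radius, ac$a_c[i],
                    s$EBc[i], total, cell$expression, variant, params)
  }, numeric(1)) else numeric(0)
  # limit EB outflow (dissociation + all exocytosis) against the EB pool
  out_EB <- diss + sum(c_i)
  if (out_EB * h > cell$EB && out_EB > 0) {
    scale <- cell$EB / (out_EB * h)
    diss <- diss * scale
    c_i <- c_i * scale
  }
  d_i <- if (n) params$rho_d * ac$a_d * s$EBc else numeric(0)
  # pairwise redistribution transfers, limited per donor site
  transfer <- matrix(0, n, n)
  if (variant != "model1" && n > 1) {
    gam <- params$gamma
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (s$EBc[i] > s$EBc[j]) transfer[i, j] <- gam * (s$EBc[i] - s$EBc[j])
    }
  }
  if (n) {
    out_site <- d_i + rowSums(transfer)
    for (i in seq_len(n)) {
      if (out_site[i] * h > s$EBc[i] && out_site[i] > 0) {
        scale <- s$EBc[i] / (out_site[i] * h)
        d_i[i] <- d_i[i] * scale
        transfer[i, ] <- transfer[i, ] * scale
      }
    }
  }
  r_in <- if (n) colSums(transfer) else numeric(0)
  r_out <- if (n) rowSums(transfer) else numeric(0)
  cell$E <- cell$E + h * (-bind + diss)
  cell$B <- cell$B + h * (-bind + diss)
  cell$EB <- cell$EB + h * (bind - diss - sum(c_i) + sum(d_i))
  if (n) cell$sites$EBc <- s$EBc + h * (c_i - d_i + r_in - r_out)
  # flux limiting keeps pools non-negative up to round-off; snap tiny noise
  cell$E <- max(cell$E, 0); cell$B <- max(cell$B, 0); cell$EB <- max(cell$EB, 0)
  cell
}
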