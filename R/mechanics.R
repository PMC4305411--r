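# Cell-cell mechanics: Hertz repulsion, bond-to-force maps, net force and
# pressure, overdamped motion. Units: um, min, pN (1 Pa = 1 pN/um^2).

#' Hertz contact repulsion between two elastic spheres
#'
#' Classical Hertz theory for two compressed spheres. With overlap
#' `h = max(0, R_i + R_j - d)` the repulsive force is
#' \deqn{F = \frac{h^{3/2} \sqrt{R_i R_j / (R_i + R_j)}}
#'           {\tfrac{3}{4}\left(\frac{1-\sigma_i^2}{E_i} +
#'            \frac{1-\sigma_j^2}{E_j}\right)}}
#' in pN when lengths are in um and moduli in Pa. The force is the negative
#' derivative of the Hertz potential
#' `V = (2/5) h^{5/2} sqrt(R_i R_j/(R_i+R_j)) / ((3/4)(...))`, is zero at
#' zero overlap and strictly increasing in the overlap. With the default
#' parameters (R = 5 um, sigma = 1/3, E = 1 kPa) a pair at 8.5 um distance
#' repels with ~2.18e3 pN; six such neighbours sum to ~13 000 pN, the
#' contact-inhibition pressure threshold.
#'
#' @param d centre distance, um (vectorized).
#' @param R_i,R_j radii, um.
#' @param sigma_i,sigma_j Poisson ratios.
#' @param E_i,E_j elastic moduli, Pa.
#' @return Repulsive force magnitude, pN.
#' @examples
#' hertz_force(8.5, 5, 5)  # ~2178 pN
#' @export
hertz_force <- function(d, R_i, R_j, sigma_i = 1 / 3, sigma_j = 1 / 3,
                        E_i = 1000, E_j = 1000) {
  stopifnot(all(d >= 0), R_i > 0, R_j > 0, E_i > 0, E_j > 0)
  h <- pmax(0, R_i + R_j - d)
  pref <- sqrt(R_i * R_j / (R_i + R_j)) /
    (0.75 * ((1 - sigma_i^2) / E_i + (1 - sigma_j^2) / E_j))
  h^1.5 * pref
}

#' Hertz contact potential
#'
#' The potential whose negative distance derivative is [hertz_force()];
#' provided for energy-based diagnostics.
#'
#' @inheritParams hertz_force
#' @return Potential, pN um.
#' @export
hertz_potential <- function(d, R_i, R_j, sigma_i = 1 / 3, sigma_j = 1 / 3,
                            E_i = 1000, E_j = 1000) {
  h <- pmax(0, R_i + R_j - d)
  pref <- sqrt(R_i * R_j / (R_i + R_j)) /
    (0.75 * ((1 - sigma_i^2) / E_i + (1 - sigma_j^2) / E_j))
  0.4 * h^2.5 * pref
}

#' Bond-to-force map: adhesive/separation force between two cells
#'
#' The number of trans bonds a pair can form is limited by the poorer of the
#' two contact compartments, `m = min(pct_self, pct_partner)` (% of maximum
#' complexes). The force is linear in `m` and anchored at the dual-pipette
#' separation force of 210 nN: Model 1 reaches 210 nN at `m = 15` (its
#' per-site ceiling is `expression/6`), Models 2 and 3 at `m = 80` (the
#' global saturation level). The map is deliberately uncapped: `m` above the
#' anchor extrapolates linearly.
#'
#' Model 3 reinterprets bonds as resisting separation only: the force is
#' zero whenever the cells are at or inside their natural-state distance
#' (contact circle at least one sixth of the circumference; see
#' [natural_state_distance()], generalized to unequal radii via the mean
#' radius), and equals the Model 2 value beyond it.
#'
#' @param variant `"model1"`, `"model2"` or `"model3"`.
#' @param pct_self,pct_partner bound-complex levels of the two facing
#'   contact compartments, %.
#' @param d centre distance, um (used by Model 3 only).
#' @param R_i,R_j radii, um (used by Model 3 only).
#' @return Force magnitude, pN (210 nN = 210 000 pN at the anchor).
#' @examples
#' adhesion_force("model2", 80, 80)          # 210000 pN
#' adhesion_force("model1", 15, 15)          # 210000 pN
#' adhesion_force("model3", 80, 80, d = 8)   # 0: inside natural state
#' @export
adhesion_force <- function(variant, pct_self, pct_partner, d = NULL,
                           R_i = 5, R_j = 5) {
  variant <- check_variant(variant)
  stopifnot(all(pct_self >= 0), all(pct_partner >= 0))
  m <- pmin(pct_self, pct_partner)
  f <- m / anchor_pct(variant) * FORCE_REF_PN
  if (variant == "model3") {
    if (is.null(d)) stop("model3 requires the centre distance d")
    f <- ifelse(d <= natural_state_distance((R_i + R_j) / 2), 0, f)
  }
  f
}

#' Net force and pressure on one cell
#'
#' Sums the pairwise interactions of `cell_id` with all other cells in a
#' world: Hertz repulsion along the centre line for every geometric overlap
#' and the variant's adhesive force along the centre line for every contact
#' site. The M-phase sibling pair is skipped (dumb-bell suppression). The
#' scalar `pressure` is the sum of the repulsive magnitudes, the quantity
#' compared against the 13 000 pN contact-inhibition threshold.
#'
#' @param cell_id identifier of the cell of interest.
#' @param world a `colony_world` (see [build_world()]).
#' @param variant model variant name.
#' @param mech [mech_params()].
#' @return List with `force` (2-vector, pN) and `pressure` (scalar, pN).
#' @examples
#' w <- make_hexagon_world()
#' net_force_and_pressure(1, w, "model2", mech_params())
#' @export
net_force_and_pressure <- function(cell_id, world, variant, mech = mech_params()) {
  variant <- check_variant(variant)
  cells <- world$cells
  i <- match(cell_id, cells$id)
  if (is.na(i)) stop("unknown cell id")
  force <- c(0, 0)
  pressure <- 0
  sib <- cells$sibling[i]
  for (j in seq_len(nrow(cells))) {
    if (j == i) next
    if (!is.na(sib) && cells$id[j] == sib &&
        cells$phase[i] == "M" && cells$phase[j] == "M") next
    dx <- cells$x[j] - cells$x[i]
    dy <- cells$y[j] - cells$y[i]
    d <- sqrt(dx^2 + dy^2)
    if (d < 1e-12) next
    u <- c(dx, dy) / d
    rep_f <- hertz_force(d, cells$radius[i], cells$radius[j],
                         mech$sigma, mech$sigma, mech$E_mod, mech$E_mod)
    adh_f <- 0
    site <- which(world$contacts$cell_i == cells$id[i] &
                    world$contacts$cell_j == cells$id[j] |
                  world$contacts$cell_j == cells$id[i] &
                    world$contacts$cell_i == cells$id[j])
    if (length(site)) {
      con <- world$contacts[site[1], ]
      if (con$cell_i == cells$id[i]) {
        self <- con$EBc_i; partner <- con$EBc_j
      } else {
        self <- con$EBc_j; partner <- con$EBc_i
      }
      adh_f <- adhesion_force(variant, self, partner, d,
                              cells$radius[i], cells$radius[j])
    }
    force <- force + (adh_f - rep_f) * u
    pressure <- pressure + abs(rep_f)
  }
  list(force = force, pressure = pressure)
}

#' Stokes drag coefficient of a cell
#'
#' `6 pi eta R` converted to pN min / um: with the default viscosity of
#' 10 Pa s and R = 5 um this is ~15.71 pN min/um (942.5 pN s/um), so a
#' constant force of 942.5 pN moves a cell at 1 um/s.
#'
#' @param radius cell radius, um.
#' @param eta medium viscosity, Pa s.
#' @return Drag coefficient, pN min / um.
#' @examples
#' stokes_drag(5, 10)
#' @export
stokes_drag <- function(radius, eta = 10) {
  6 * pi * (eta / 60) * radius
}

#' One overdamped motion step for an R-level world
#'
#' Explicit-Euler update of all cell positions under the current pairwise
#' forces, `x <- x + dt * F / (6 pi eta R)`, with displacement-capped
#' sub-stepping: no cell moves more than `cap` um per substep. An isotropic
#' zero-mean Gaussian random force of amplitude `mech$noise_amp` (pN per
#' component) is drawn once per call when enabled. This is the reference
#' R implementation used by the small-scenario tests; colony runs use the
#' compiled engine.
#'
#' Under `"model3"` the bonds act as separation constraints rather than
#' active pulls: positions are first driven by repulsion (and noise) alone,
#' then for every bonded pair beyond its natural-state distance the
#' separating component of the relative velocity is cancelled by an
#' equal-and-opposite centre-line force capped at the bond separation
#' force. Bonds never compress; a pair separates only when driven harder
#' than its bond force.
#'
#' @param world a `colony_world`.
#' @param dt time step, min.
#' @param variant model variant name.
#' @param mech [mech_params()].
#' @param cap displacement cap per substep, um.
#' @param max_substeps upper bound on substeps per call.
#' @param min_distance_frac pairs are kept at least this fraction of
#'   `R_i + R_j` apart (keeps centre-line directions defined when adhesion
#'   overwhelms repulsion).
#' @return The world with updated positions.
#' @export
motion_step <- function(world, dt, variant, mech = mech_params(),
                        cap = 0.05, max_substeps = 50L,
                        min_distance_frac = 0.1) {
  variant <- check_variant(variant)
  stopifnot(dt > 0)
  n <- nrow(world$cells)
  if (n == 0) return(world)
  noise <- matrix(0, n, 2)
  if (mech$noise_amp > 0) noise <- matrix(rnorm(2 * n, 0, mech$noise_amp), n, 2)
  remaining <- dt
  steps <- 0L
  while (remaining > 1e-12 && steps < max_substeps) {
    steps <- steps + 1L
    wf <- world
    if (variant == "model3" && nrow(wf$contacts)) {
      wf$contacts$EBc_i <- 0  # repulsion only; bonds applied as constraints
      wf$contacts$EBc_j <- 0
    }
    fp <- lapply(wf$cells$id, function(id)
      net_force_and_pressure(id, wf, variant, mech))
    vel <- t(vapply(seq_len(n), function(i)
      (fp[[i]]$force + noise[i, ]) / stokes_drag(world$cells$radius[i], mech$eta),
      numeric(2)))
    if (variant == "model3") {
      vel <- apply_separation_constraint(world, vel, mech)
    }
    vmax <- max(sqrt(rowSums(vel^2)), 0)
    dt_s <- if (vmax > 0) min(remaining, cap / vmax) else remaining
    disp <- vel * dt_s
    # clamp any displacement to the cap (terminal crush velocity)
    mag <- sqrt(rowSums(disp^2))
    over <- mag > cap
    if (any(over)) disp[over, ] <- disp[over, ] * (cap / mag[over])
    px <- world$cells$x
    py <- world$cells$y
    world$cells$x <- world$cells$x + disp[, 1]
    world$cells$y <- world$cells$y + disp[, 2]
    world <- enforce_min_distance(world, min_distance_frac)
    remaining <- remaining - dt_s
    # pinned/equilibrated within the step: no further sub-step can move
    if (max(abs(world$cells$x - px), abs(world$cells$y - py)) < 1e-7) break
  }
  world$cells$pressure <- vapply(world$cells$id, function(id)
    net_force_and_pressure(id, world, variant, mech)$pressure, numeric(1))
  world
}

# Model 3: cancel the separating component of bonded pairs' relative
# velocities with a centre-line force capped at the bond separation force
apply_separation_constraint <- function(world, vel, mech, sweeps = 4) {
  cells <- world$cells
  con <- world$contacts
  if (!nrow(con)) return(vel)
  i_idx <- match(con$cell_i, cells$id)
  j_idx <- match(con$cell_j, cells$id)
  keep <- !is.na(i_idx) & !is.na(j_idx)
  used <- numeric(nrow(con))
  for (sweep in seq_len(sweeps)) {
    for (r in which(keep)) {
      i <- i_idx[r]; j <- j_idx[r]
      m <- min(con$EBc_i[r], con$EBc_j[r])
      if (m <= 0) next
      dx <- cells$x[j] - cells$x[i]
      dy <- cells$y[j] - cells$y[i]
      d <- sqrt(dx^2 + dy^2)
      if (d < 1e-9 ||
          d <= natural_state_distance((cells$radius[i] + cells$radius[j]) / 2))
        next
      u <- c(dx, dy) / d
      gi <- stokes_drag(cells$radius[i], mech$eta)
      gj <- stokes_drag(cells$radius[j], mech$eta)
      s <- sum((vel[j, ] - vel[i, ]) * u)
      budget <- adhesion_force("model2", con$EBc_i[r], con$EBc_j[r])
      if (s > 0) {
        f <- min(s / (1 / gi + 1 / gj), budget - used[r])
      } else if (used[r] > 0 && s < 0) {
        f <- max(s / (1 / gi + 1 / gj), -used[r])
      } else next
      used[r] <- used[r] + f
      vel[i, ] <- vel[i, ] + f / gi * u
      vel[j, ] <- vel[j, ] - f / gj * u
    }
  }
  vel
}

enforce_min_distance <- function(world, frac) {
  cells <- world$cells
  n <- nrow(cells)
  if (n < 2 || frac <= 0) return(world)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    dmin <- frac * (cells$radius[i] + cells$radius[j])
    dx <- cells$x[j] - cells$x[i]
    dy <- cells$y[j] - cells$y[i]
    d <- sqrt(dx^2 + dy^2)
    if (d < dmin) {
      if (d < 1e-9) { dx <- dmin; dy <- 0; d <- dmin }
      push <- (dmin - d) / 2
      ux <- dx / d; uy <- dy / d
      cells$x[i] <- cells$x[i] - ux * push
      cells$y[i] <- cells$y[i] - uy * push
      cells$x[j] <- cells$x[j] + ux * push
      cells$y[j] <- cells$y[j] + uy * push
    }
  }
  world$cells <- cells
  world
}
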