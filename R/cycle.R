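# Stochastic cell cycle: G1 growth -> rest (G0/S/G2) -> M (dumb-bell) ->
# division, with pressure-triggered arrest at the rest-to-M boundary.

#' Draw a rest-phase duration
#'
#' The combined G0/S/G2 phase lasts uniformly between `rest_min` and
#' `rest_max` (default 8-18 h), giving total generation times of 17-27 h.
#'
#' @param cycle [cycle_params()].
#' @param n number of draws.
#' @return Durations in minutes.
#' @export
draw_rest_duration <- function(cycle = cycle_params(), n = 1) {
  runif(n, cycle$rest_min, cycle$rest_max)
}

#' Advance the cycle state of one cell
#'
#' G1: the radius grows linearly from `R / 2^(1/3)` to `R` over `t_G1`.
#' REST: the cell idles for its drawn `rest_duration`; at the rest-to-M
#' boundary the transition is blocked (`arrested = TRUE`, re-checked every
#' step) while `pressure > threshold` and contact inhibition is enabled.
#' M: the dumb-bell phase runs for `t_M`, after which the cell enters G1
#' and its sibling link is cleared. Division itself (replacing a cell by
#' two daughters) happens at M entry; see [divide_cell()]. The return flags
#' `divide = TRUE` when the cell passed the rest-to-M boundary this step.
#'
#' @param cell a list with at least `phase`, `phase_clock`, `rest_duration`,
#'   `radius` (e.g. a row of `world$cells` as a list, or a [new_cell()]).
#' @param dt time step, min.
#' @param pressure current pressure on the cell, pN.
#' @param cycle [cycle_params()].
#' @param R_max maximum cell radius, um.
#' @param contact_inhibition enable the pressure gate.
#' @param pressure_threshold arrest threshold, pN.
#' @return List `(cell, divide)`.
#' @export
advance_cycle <- function(cell, dt, pressure, cycle = cycle_params(),
                          R_max = 5, contact_inhibition = FALSE,
                          pressure_threshold = 13000) {
  stopifnot(dt > 0)
  divide <- FALSE
  R_div <- R_max / 2^(1 / 3)
  if (cell$phase == "M") {
    cell$phase_clock <- cell$phase_clock + dt
    if (cell$phase_clock >= cycle$t_M) {
      cell$phase <- "G1"
      cell$phase_clock <- 0
      cell$sibling <- NA_integer_
    }
  } else if (cell$phase == "G1") {
    cell$phase_clock <- cell$phase_clock + dt
    frac <- min(1, cell$phase_clock / cycle$t_G1)
    cell$radius <- R_div + (R_max - R_div) * frac
    if (cell$phase_clock >= cycle$t_G1) {
      cell$phase <- "REST"
      cell$phase_clock <- 0
      if (is.na(cell$rest_duration)) {
        cell$rest_duration <- draw_rest_duration(cycle)
      }
    }
  } else { # REST
    cell$radius <- R_max
    if (is.na(cell$rest_duration)) cell$rest_duration <- draw_rest_duration(cycle)
    cell$phase_clock <- cell$phase_clock + dt
    if (cell$phase_clock >= cell$rest_duration) {
      if (contact_inhibition && pressure > pressure_threshold) {
        cell$arrested <- TRUE          # hold at the boundary; re-check next step
      } else {
        cell$arrested <- FALSE
        divide <- TRUE
      }
    }
  }
  list(cell = cell, divide = divide)
}

#' Division axis from the local compression pattern
#'
#' The axis of highest pressure is taken as the principal eigenvector of
#' the 2x2 compression tensor `sum_j |F_rep,j| (u_j x u_j)` built from the
#' repulsive contact forces on the dividing cell (`u_j` the unit centre-line
#' vectors). With no compressed neighbours (or a perfectly isotropic
#' tensor) the axis is drawn uniformly at random.
#'
#' @param rep_forces numeric vector of repulsive force magnitudes, pN.
#' @param directions 2-column matrix of unit centre-line vectors.
#' @return Unit 2-vector.
#' @export
division_axis <- function(rep_forces, directions) {
  if (length(rep_forces) == 0 || sum(rep_forces) <= 0) {
    ang <- runif(1, 0, 2 * pi)
    return(c(cos(ang), sin(ang)))
  }
  M <- matrix(0, 2, 2)
  for (k in seq_along(rep_forces)) {
    u <- directions[k, ]
    M <- M + rep_forces[k] * tcrossprod(u)
  }
  eg <- eigen(M, symmetric = TRUE)
  if (abs(eg$values[1] - eg$values[2]) < 1e-12 * max(abs(eg$values), 1)) {
    ang <- runif(1, 0, 2 * pi)
    return(c(cos(ang), sin(ang)))
  }
  v <- eg$vectors[, 1]
  v / sqrt(sum(v^2))
}

#' Divide a cell into two daughters
#'
#' Both daughters get radius `R_max / 2^(1/3)` (exact volume conservation:
#' two spheres of that radius have the parent's volume), are placed at the
#' parent position plus/minus `R_max / 2` along the division axis, enter
#' M phase as mutually non-interacting dumb-bell siblings, and inherit the
#' parent's pathway concentrations with the parent's contact-bound
#' complexes folded back into the cytosolic pool first (concentrations are
#' intensive, and the fold-back keeps `E + EB + sum(EBc)` equal to the
#' expression level in each daughter). Contact sites are re-formed by the
#' next bookkeeping pass.
#'
#' @param cell a list with `x`, `y`, `expression`, `E`, `B`, `EB` and
#'   (optionally) `sites`.
#' @param axis unit 2-vector, e.g. from [division_axis()].
#' @param ids integer ids for the daughters.
#' @param R_max maximum cell radius, um.
#' @return List of two daughter cells (lists).
#' @examples
#' divide_cell(new_cell(1, 0, 0), c(1, 0), ids = c(2L, 3L))
#' @export
divide_cell <- function(cell, axis, ids, R_max = 5) {
  stopifnot(length(ids) == 2, abs(sqrt(sum(axis^2)) - 1) < 1e-6)
  EB_pool <- cell$EB + sum(cell$sites$EBc %||% 0)
  offset <- R_max / 2
  daughter <- function(id, sgn) {
    list(id = as.integer(id),
         x = cell$x + sgn * offset * axis[1],
         y = cell$y + sgn * offset * axis[2],
         radius = R_max / 2^(1 / 3),
         expression = cell$expression,
         E = cell$E, B = cell$B, EB = EB_pool,
         sites = data.frame(partner = integer(), area = numeric(),
                            prev_area = numeric(), EBc = numeric()),
         phase = "M", phase_clock = 0, rest_duration = NA_real_,
         arrested = FALSE, sibling = as.integer(ids[ids != id]))
  }
  list(daughter(ids[1], +1), daughter(ids[2], -1))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
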