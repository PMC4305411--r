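#' Sphere-sphere contact geometry
#'
#' Cells are modelled as spheres; two overlapping spheres intersect in a
#' circle and the area of the disc bounded by that circle is taken as the
#' cell-cell contact area. For centre distance `d` and radii `R_i`, `R_j`
#' the intersection-circle radius `a` satisfies
#' `a^2 = (4 d^2 R_i^2 - (d^2 - R_j^2 + R_i^2)^2) / (4 d^2)`,
#' which for equal spheres reduces to the lens formula `a^2 = R^2 - (d/2)^2`.
#' When one sphere is engulfed by the other (`d <= |R_i - R_j|`) the contact
#' radius is capped at the smaller sphere's great circle.
#'
#' @param d centre-to-centre distance, um (vectorized).
#' @param R_i,R_j sphere radii, um.
#' @return A data.frame with columns `overlap` (um), `contact_radius` (um)
#'   and `contact_area` (um^2); all zero when the spheres do not overlap.
#' @examples
#' contact_geometry(10, 5, 5)    # tangent: all zero
#' contact_geometry(9.8, 5, 5)   # contact radius ~0.995 um
#' @export
contact_geometry <- function(d, R_i, R_j) {
  if (any(d < 0)) stop("centre distance d must be non-negative")
  stopifnot(R_i > 0, R_j > 0)
  n <- length(d)
  overlap <- pmax(0, R_i + R_j - d)
  a2 <- numeric(n)
  touching <- d < (R_i + R_j)
  inside <- d <= abs(R_i - R_j)
  lens <- touching & !inside
  if (any(lens)) {
    dl <- d[lens]
    a2[lens] <- (4 * dl^2 * R_i^2 - (dl^2 - R_j^2 + R_i^2)^2) / (4 * dl^2)
  }
  a2[inside] <- min(R_i, R_j)^2
  a2 <- pmin(pmax(a2, 0), min(R_i, R_j)^2)
  data.frame(overlap = overlap,
             contact_radius = sqrt(a2),
             contact_area = pi * a2)
}

#' Natural-state distance of two equal cells
#'
#' The "natural state" of a cell in a monolayer is the configuration in
#' which the diameter of its cell-cell contact circle equals one sixth of
#' its circumference, i.e. `2 a = 2 pi R / 6`. For two equal spheres of
#' radius `R` this happens at centre distance
#' `d* = 2 sqrt(R^2 - (pi R / 6)^2)`, about 8.52 um for `R` = 5 um, which is
#' the ~8.5 um spacing of a cell with six neighbours. In Model 3 the
#' adhesive force vanishes at and inside this distance.
#'
#' @param R cell radius, um (vectorized).
#' @return Centre-to-centre distance, um.
#' @examples
#' natural_state_distance(5)  # ~8.52
#' @export
natural_state_distance <- function(R) {
  stopifnot(R > 0)
  2 * sqrt(R^2 - (pi * R / 6)^2)
}

#' Centre distance realizing a prescribed contact area
#'
#' Inverse of [contact_geometry()]: the distance at which two overlapping
#' spheres share a contact disc of the requested area. Used to set up
#' dual-pipette scenarios that start from a 1 um^2 contact.
#'
#' @param area contact area, um^2; must be attainable
#'   (`area <= pi * min(R_i, R_j)^2`).
#' @param R_i,R_j sphere radii, um.
#' @return Centre-to-centre distance, um.
#' @examples
#' distance_for_contact_area(1, 5, 5)  # ~9.936
#' @export
distance_for_contact_area <- function(area, R_i, R_j) {
  stopifnot(area >= 0, R_i > 0, R_j > 0)
  a2 <- area / pi
  if (a2 > min(R_i, R_j)^2) stop("requested contact area exceeds the smaller sphere")
  sqrt(R_i^2 - a2) + sqrt(R_j^2 - a2)
}
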