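# Named scenario builders: the standard configurations used for
# calibration and colony studies.

#' Build a named scenario configuration
#'
#' Available scenarios:
#' \describe{
#'   \item{`two_cell`}{the dual-pipette set-up: two cells of radius 5 um
#'     placed with an initial total contact area of 1 um^2, followed for
#'     100 min with the cell cycle frozen and noise off.}
#'   \item{`three_cell_simultaneous`}{a centre cell contacted by two
#'     neighbours (initial area 1 um^2 each) at the same instant; used to
#'     require each per-site force to reach half the two-cell force.}
#'   \item{`three_cell_staggered`}{one neighbour in contact from t = 0;
#'     the second is brought into contact (area 1 um^2) at t = 20 min;
#'     used to require force equalization by ~30 min after arrival.}
#'   \item{`single_cell_colony`}{one cell at the origin starting at a
#'     random point of its cycle; 7-day horizon with daily snapshots plus
#'     forced 3-day and 7-day evaluation snapshots.}
#'   \item{`hexagon_test`}{a centre cell with six neighbours at 8.5 um,
#'     mechanics only; the configuration defining the 13 000 pN pressure
#'     threshold.}
#' }
#'
#' @param name scenario name.
#' @param variant model variant name.
#' @param expression E-cadherin expression level of all initial cells, %.
#' @param overrides named list merged into the [run_config()] arguments
#'   (e.g. `list(duration = 60, seed = 7)`).
#' @return A `run_config`.
#' @examples
#' make_scenario("two_cell")
#' make_scenario("single_cell_colony", variant = "model3",
#'               overrides = list(kinetic = kinetic_params(rho_d = 0.6)))
#' @export
make_scenario <- function(name, variant = "model2", expression = 100,
                          overrides = list()) {
  name <- match.arg(name, c("two_cell", "three_cell_simultaneous",
                            "three_cell_staggered", "single_cell_colony",
                            "hexagon_test"))
  R <- 5
  d1 <- distance_for_contact_area(1, R, R)
  two <- function(...) {
    data.frame(x = c(0, d1), y = c(0, 0), radius = R,
               expression = expression, phase = "REST")
  }
  args <- switch(name,
    two_cell = list(
      variant = variant, duration = 100, snapshot_interval = 1,
      cycle_enabled = FALSE, collapse_check = FALSE,
      cells = two()),
    three_cell_simultaneous = list(
      variant = variant, duration = 100, snapshot_interval = 1,
      cycle_enabled = FALSE, collapse_check = FALSE,
      cells = data.frame(x = c(0, -d1, d1), y = c(0, 0, 0), radius = R,
                         expression = expression, phase = "REST")),
    three_cell_staggered = list(
      variant = variant, duration = 100, snapshot_interval = 1,
      cycle_enabled = FALSE, collapse_check = FALSE,
      cells = data.frame(x = c(0, -d1), y = c(0, 0), radius = R,
                         expression = expression, phase = "REST"),
      introduce = data.frame(time = 20, target = 1L, dir_x = 1, dir_y = 0,
                             area = 1, radius = R,
                             expression = expression)),
    single_cell_colony = list(
      variant = variant, duration = 7 * 1440, snapshot_interval = 1440,
      forced_times = c(3, 7) * 1440,
      cycle_enabled = TRUE, collapse_check = TRUE,
      cells = NULL),
    hexagon_test = {
      ang <- seq(0, 5) * pi / 3
      list(variant = variant, duration = 1, snapshot_interval = 1,
           cycle_enabled = FALSE, collapse_check = TRUE,
           cells = data.frame(x = c(0, 8.5 * cos(ang)),
                              y = c(0, 8.5 * sin(ang)),
                              radius = R, expression = expression,
                              phase = "REST"))
    })
  args$scenario <- name
  args <- modifyList(args, overrides)
  do.call(run_config, args)
}
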