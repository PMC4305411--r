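# Run orchestration: configuration objects, the compiled main loop, and the
# trajectory container.

#' Build a run configuration
#'
#' Collects everything a reproducible run needs: model variant, parameter
#' sets, operator-splitting step sizes, run length, seed, snapshot times and
#' the initial cell layout. The engine advances the world in pathway steps
#' of `dt` minutes (bookkeeping, pathway integration, mechanics
#' sub-stepping, cycle progression, collapse check), so a run is fully
#' determined by `(config, seed)`.
#'
#' @param variant `"model1"`, `"model2"` or `"model3"`.
#' @param kinetic [kinetic_params()].
#' @param mech [mech_params()].
#' @param cycle [cycle_params()].
#' @param duration run length, min.
#' @param dt pathway time step, min (bookkeeping interval of the contact
#'   areas; mechanics sub-steps within it).
#' @param seed integer seed; every random draw of the run flows from it.
#' @param snapshot_interval interval between stored snapshots, min (0 =
#'   only forced/final snapshots).
#' @param forced_times extra times (min) at which a snapshot is always
#'   taken, e.g. the 3-day and 7-day evaluation points of colony runs.
#' @param contact_inhibition gate the rest-to-M transition on pressure.
#' @param cycle_enabled advance the cell cycle at all (dual-pipette
#'   scenarios freeze it).
#' @param collapse_check halt when two cells interpenetrate beyond
#'   `collapse_frac * (R_i + R_j)`.
#' @param collapse_frac collapse threshold fraction.
#' @param displacement_cap maximum displacement per mechanics substep, um.
#' @param max_substeps mechanics substeps per pathway step.
#' @param min_distance_frac minimum pair distance as a fraction of
#'   `R_i + R_j`, enforced only when `collapse_check` is off.
#' @param drain_tol bound-complex level below which detached contact sites
#'   are deleted, %.
#' @param cells optional data.frame of initial cells (see [build_world()]);
#'   default: a single cell at the origin starting at a uniformly random
#'   point of its G1/rest cycle.
#' @param introduce optional data.frame of scheduled cell introductions
#'   with columns `time` (min), `target` (cell id), `dir_x`, `dir_y`
#'   (placement direction), `area` (initial contact area, um^2), `radius`,
#'   `expression`.
#' @param scenario optional scenario name (bookkeeping only).
#' @return An object of class `run_config`.
#' @examples
#' run_config(duration = 10, cells = data.frame(x = 0, y = 0))
#' @export
run_config <- function(variant = "model2", kinetic = kinetic_params(),
                       mech = mech_params(), cycle = cycle_params(),
                       duration = 100, dt = 0.01, seed = 1L,
                       snapshot_interval = 10, forced_times = numeric(),
                       contact_inhibition = FALSE, cycle_enabled = TRUE,
                       collapse_check = TRUE, collapse_frac = 0.2,
                       displacement_cap = 0.05, max_substeps = 50L,
                       min_distance_frac = 0.1, drain_tol = 1e-6,
                       cells = NULL, introduce = NULL,
                       scenario = NA_character_) {
  stopifnot(duration >= 0, dt > 0, snapshot_interval >= 0,
            displacement_cap > 0, max_substeps >= 1)
  structure(list(
    variant = check_variant(variant),
    kinetic = as_kinetic_params(kinetic),
    mech = as_mech_params(mech),
    cycle = as_cycle_params(cycle),
    duration = duration, dt = dt, seed = as.integer(seed),
    snapshot_interval = snapshot_interval,
    forced_times = as.numeric(forced_times),
    contact_inhibition = isTRUE(contact_inhibition),
    cycle_enabled = isTRUE(cycle_enabled),
    collapse_check = isTRUE(collapse_check),
    collapse_frac = collapse_frac,
    displacement_cap = displacement_cap,
    max_substeps = as.integer(max_substeps),
    min_distance_frac = min_distance_frac,
    drain_tol = drain_tol,
    cells = cells, introduce = introduce,
    scenario = scenario
  ), class = "run_config")
}

#' @export
print.run_config <- function(x, ...) {
  cat("<run_config>", x$variant, "| duration", x$duration, "min | dt", x$dt,
      "min | seed", x$seed, "\n")
  cat("  contact inhibition:", x$contact_inhibition,
      "| cycle:", x$cycle_enabled, "| collapse check:", x$collapse_check, "\n")
  invisible(x)
}

#' Run a colony simulation
#'
#' Executes the configured run in the compiled engine: per pathway step the
#' contact table is updated, every cell's pathway is advanced by forward
#' Euler with conservation-exact flux limiting, positions are moved by the
#' overdamped equation of motion with displacement-capped sub-stepping, the
#' cell cycle progresses (divisions replace a mother by two dumb-bell
#' daughters at M entry), and the collapse detector may halt the run.
#' Identical `(config, seed)` give bit-identical trajectories.
#'
#' @param config a [run_config()] (or [make_scenario()] result).
#' @return A `colony_trajectory`: list with `snapshots` (list of
#'   `colony_world`), `metrics` (per-snapshot data.frame), `status`
#'   (`"done"` or `"collapsed"`), and the `config`.
#' @examples
#' traj <- run_colony(make_scenario("two_cell", overrides = list(duration = 5)))
#' tail(traj$metrics)
#' @export
run_colony <- function(config) {
  stopifnot(inherits(config, "run_config"))
  set.seed(config$seed)
  cells <- config$cells
  if (is.null(cells)) cells <- random_phase_cell(config)
  world0 <- build_world(cells, bookkeep = TRUE)
  cdf <- world0$cells
  cdf$phase_code <- match(cdf$phase, c("G1", "REST", "M")) - 1L
  intro <- config$introduce
  if (is.null(intro)) {
    intro <- data.frame(time = numeric(), target = integer(),
                        dir_x = numeric(), dir_y = numeric(),
                        area = numeric(), radius = numeric(),
                        expression = numeric())
  }
  n_steps <- round(config$duration / config$dt)
  forced <- unique(c(round(config$forced_times / config$dt), n_steps))
  forced <- forced[forced >= 0 & forced <= n_steps]
  cfg <- list(
    variant_code = match(config$variant, variant_names()),
    kinetic = unclass(config$kinetic),
    mech = unclass(config$mech),
    cycle = unclass(config$cycle),
    contact_inhibition = config$contact_inhibition,
    cycle_enabled = config$cycle_enabled,
    collapse_check = config$collapse_check,
    collapse_frac = config$collapse_frac,
    dt = config$dt,
    displacement_cap = config$displacement_cap,
    min_distance_frac = config$min_distance_frac,
    drain_tol = config$drain_tol,
    max_substeps = config$max_substeps,
    sat_fraction = MODEL2_SAT_FRACTION,
    n_steps = as.numeric(n_steps),
    snap_every = if (config$snapshot_interval > 0)
      as.integer(round(config$snapshot_interval / config$dt)) else 0L,
    forced_steps = as.integer(forced),
    introduce = intro
  )
  t0 <- proc.time()[["elapsed"]]
  res <- cpp_run_colony(cdf, world0$contacts, cfg)
  wall <- proc.time()[["elapsed"]] - t0
  snaps <- lapply(res$snapshots, function(s) {
    structure(list(cells = s$cells, contacts = s$contacts,
                   time = s$time, status = s$status),
              class = "colony_world")
  })
  if (length(snaps)) snaps[[length(snaps)]]$status <- res$status
  metrics <- do.call(rbind, lapply(snaps, function(w) {
    data.frame(time = w$time,
               n_cells = nrow(w$cells),
               mean_contact_force = mean_contact_force(w, config$variant),
               mean_free_E = mean(w$cells$E),
               status = w$status)
  }))
  structure(list(snapshots = snaps, metrics = metrics,
                 status = res$status, wall_time = wall, config = config),
            class = "colony_trajectory")
}

random_phase_cell <- function(config) {
  cyc <- config$cycle
  R <- config$mech$R
  rest <- draw_rest_duration(cyc)
  u <- runif(1, 0, cyc$t_G1 + rest)
  R_div <- R / 2^(1 / 3)
  if (u < cyc$t_G1) {
    data.frame(x = 0, y = 0, phase = "G1", phase_clock = u,
               radius = R_div + (R - R_div) * u / cyc$t_G1,
               rest_duration = rest)
  } else {
    data.frame(x = 0, y = 0, phase = "REST", phase_clock = u - cyc$t_G1,
               radius = R, rest_duration = rest)
  }
}

#' @export
print.colony_trajectory <- function(x, ...) {
  last <- x$snapshots[[length(x$snapshots)]]
  cat("<colony_trajectory>", length(x$snapshots), "snapshots over",
      x$config$duration, "min |", x$status, "\n")
  cat("  final:", nrow(last$cells), "cells at t =", last$time, "min\n")
  invisible(x)
}

#' Extract the snapshot closest to a given time
#'
#' @param trajectory a `colony_trajectory`.
#' @param time requested time, min (default: last snapshot).
#' @return A `colony_world`.
#' @export
snapshot_at <- function(trajectory, time = NULL) {
  times <- vapply(trajectory$snapshots, `[[`, numeric(1), "time")
  if (is.null(time)) return(trajectory$snapshots[[length(times)]])
  trajectory$snapshots[[which.min(abs(times - time))]]
}
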