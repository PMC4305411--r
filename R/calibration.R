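# Dual-pipette calibration: simulate separation-force curves, fit the four
# two-cell kinetic rates by multi-start Nelder-Mead, then fit the
# redistribution rate against three-cell criteria.

#' Bundle dual-pipette force measurements
#'
#' The calibration data consist of a force-versus-time series for two cells
#' at 100% E-cadherin expression (measurements at 5, 10, 30 and 60 min of
#' contact, maturing to ~210 nN) and a force-versus-expression series taken
#' 30 min after initial contact (expression levels 100, 58, 41, 38, 14 and
#' 2%).
#'
#' @param time_series data.frame with columns `time_min`, `force_nN`.
#' @param expression_series data.frame with columns `expression_pct`,
#'   `force_nN_at_30min`.
#' @return An object of class `pipette_dataset`.
#' @export
pipette_dataset <- function(time_series, expression_series) {
  stopifnot(all(c("time_min", "force_nN") %in% names(time_series)),
            all(c("expression_pct", "force_nN_at_30min") %in%
                  names(expression_series)))
  ts <- time_series[order(time_series$time_min), , drop = FALSE]
  if (any(ts$time_min <= 0) || any(diff(ts$time_min) <= 0))
    stop("times must be positive and strictly increasing")
  if (any(ts$force_nN < 0) || any(expression_series$force_nN_at_30min < 0))
    stop("forces must be non-negative")
  structure(list(time_series = ts, expression_series = expression_series),
            class = "pipette_dataset")
}

#' @export
print.pipette_dataset <- function(x, ...) {
  cat("<pipette_dataset>", nrow(x$time_series), "time points,",
      nrow(x$expression_series), "expression levels\n")
  invisible(x)
}

#' Simulate the dual-pipette separation force between two cells
#'
#' Runs the two-cell scenario (radii 5 um, initial contact area 1 um^2,
#' noise off, mechanics on, cell cycle frozen) for the requested horizon
#' and reports the separation force through the variant's bond-to-force
#' map. The force starts at ~0 (no bound complexes initially) and matures
#' on the tens-of-minutes scale as complexes are trafficked to the contact.
#'
#' @param params [kinetic_params()].
#' @param variant model variant name.
#' @param expression E-cadherin expression level, % in (0, 100].
#' @param horizon simulated time, min.
#' @param dt pathway step, min.
#' @param seed seed (the default scenario is fully deterministic; the seed
#'   only matters if noise is enabled via `mech`).
#' @param mech [mech_params()].
#' @param times optional vector of report times, min; default every minute
#'   up to the horizon. Restricting the times makes repeated calls inside
#'   fitting loops much cheaper.
#' @return data.frame with columns `time` (min) and `force_nN`.
#' @examples
#' \donttest{
#' f <- simulate_pipette_force(kinetic_params(), "model2", 100, 60)
#' f[f$time == 60, ]
#' }
#' @export
simulate_pipette_force <- function(params, variant, expression = 100,
                                   horizon = 100, dt = 0.01, seed = 1L,
                                   mech = mech_params(), times = NULL) {
  stopifnot(expression > 0, expression <= 100)
  snap <- if (is.null(times)) list(snapshot_interval = 1) else
    list(snapshot_interval = 0, forced_times = times)
  cfg <- make_scenario("two_cell", variant = variant,
                       expression = expression,
                       overrides = c(list(kinetic = params, mech = mech,
                                          duration = horizon, dt = dt,
                                          seed = seed), snap))
  traj <- run_colony(cfg)
  force <- vapply(traj$snapshots, function(w) {
    con <- w$contacts
    if (!nrow(con)) return(0)
    sum(con$force_pN) / 1000
  }, numeric(1))
  times <- vapply(traj$snapshots, `[[`, numeric(1), "time")
  data.frame(time = times, force_nN = force)
}

#' Generate a synthetic dual-pipette dataset from the model
#'
#' Produces a `pipette_dataset` by simulating the two-cell scenario at the
#' given rates — the ground-truth generator for parameter-recovery
#' experiments and the shipped synthetic fixture (the original force values
#' at 5/10/30 min and at sub-100% expression are not tabulated anywhere,
#' only the 210 nN maturation anchor is).
#'
#' @param params generating [kinetic_params()].
#' @param variant model variant name.
#' @param times measurement times, min.
#' @param expressions expression levels measured at 30 min, %.
#' @param dt pathway step, min.
#' @return A [pipette_dataset()].
#' @export
synthetic_pipette_data <- function(params = kinetic_params(),
                                   variant = "model2",
                                   times = c(5, 10, 30, 60),
                                   expressions = c(100, 58, 41, 38, 14, 2),
                                   dt = 0.01) {
  full <- simulate_pipette_force(params, variant, 100, max(times), dt = dt)
  ts <- data.frame(time_min = times,
                   force_nN = full$force_nN[match(times, full$time)])
  ex <- vapply(expressions, function(e) {
    if (e == 100) return(full$force_nN[match(30, full$time)])
    f <- simulate_pipette_force(params, variant, e, 30, dt = dt)
    f$force_nN[match(30, f$time)]
  }, numeric(1))
  pipette_dataset(ts, data.frame(expression_pct = expressions,
                                 force_nN_at_30min = ex))
}

# Lean closure over the compiled engine for fitting loops: the scenario
# skeleton (cells, contact table, step counts) is built once; only the
# kinetic rates change between calls.
make_pipette_objective <- function(data, variant, params, dt) {
  variant <- check_variant(variant)
  ts <- data$time_series
  es <- data$expression_series
  want <- sort(unique(c(ts$time_min, if (100 %in% es$expression_pct) 30)))
  d1 <- distance_for_contact_area(1, 5, 5)
  skeleton <- function(expression, horizon, times) {
    cfg <- make_scenario("two_cell", variant = variant,
                         expression = expression,
                         overrides = list(duration = horizon, dt = dt,
                                          snapshot_interval = 0,
                                          forced_times = times))
    w0 <- build_world(cfg$cells, bookkeep = TRUE)
    cdf <- w0$cells
    cdf$phase_code <- match(cdf$phase, c("G1", "REST", "M")) - 1L
    n_steps <- round(horizon / dt)
    list(cells = cdf, contacts = w0$contacts, cpp = list(
      variant_code = match(variant, variant_names()),
      kinetic = unclass(cfg$kinetic), mech = unclass(cfg$mech),
      cycle = unclass(cfg$cycle), contact_inhibition = FALSE,
      cycle_enabled = FALSE, collapse_check = FALSE, collapse_frac = 0.2,
      dt = dt, displacement_cap = cfg$displacement_cap,
      min_distance_frac = cfg$min_distance_frac, drain_tol = cfg$drain_tol,
      max_substeps = cfg$max_substeps, sat_fraction = MODEL2_SAT_FRACTION,
      n_steps = as.numeric(n_steps), snap_every = 0L,
      forced_steps = as.integer(sort(unique(round(times / dt)))),
      introduce = data.frame(time = numeric(), target = integer(),
                             dir_x = numeric(), dir_y = numeric(),
                             area = numeric(), radius = numeric(),
                             expression = numeric())),
      times = times)
  }
  skels <- list(skeleton(100, max(want), want))
  for (e in es$expression_pct) {
    if (e != 100) skels <- c(skels, list(skeleton(e, 30, 30)))
  }
  run_skel <- function(sk, rates) {
    kin <- sk$cpp$kinetic
    kin$rho_u <- rates[1]; kin$nu_n <- rates[2]
    kin$nu_p <- rates[3]; kin$rho_c <- rates[4]
    sk$cpp$kinetic <- kin
    res <- cpp_run_colony(sk$cells, sk$contacts, sk$cpp)
    vapply(res$snapshots, function(s) {
      f <- s$contacts$force_pN
      if (length(f)) sum(f) / 1000 else 0
    }, numeric(1))
  }
  function(rates) {
    if (any(!is.finite(rates)) || any(rates < 0)) return(1e12)
    f100 <- run_skel(skels[[1]], rates)
    names(f100) <- skels[[1]]$times
    obj <- sum((f100[as.character(ts$time_min)] - ts$force_nN)^2)
    k <- 1
    for (r in seq_len(nrow(es))) {
      e <- es$expression_pct[r]
      sim <- if (e == 100) f100[["30"]] else {
        k <- k + 1
        run_skel(skels[[k]], rates)[1]
      }
      obj <- obj + (sim - es$force_nN_at_30min[r])^2
    }
    obj
  }
}

#' Sum-of-squares objective of a candidate rate set
#'
#' Simulates the two-cell scenario at every expression level in the data
#' and returns the summed squared force residuals (nN^2) over both the
#' time series and the expression series. Invariant to the ordering of the
#' data points.
#'
#' @param rates numeric vector `c(rho_u, nu_n, nu_p, rho_c)`.
#' @param data a [pipette_dataset()].
#' @param variant model variant name.
#' @param params base [kinetic_params()] supplying `rho_d` and `gamma`.
#' @param dt pathway step used in the fitting simulations, min.
#' @return Scalar objective, nN^2.
#' @export
pipette_objective <- function(rates, data, variant,
                              params = kinetic_params(), dt = 0.02) {
  if (any(!is.finite(rates)) || any(rates < 0)) return(1e12)
  p <- kinetic_params(rho_u = rates[1], nu_n = rates[2], nu_p = rates[3],
                      rho_c = rates[4], rho_d = params$rho_d,
                      gamma = params$gamma)
  ts <- data$time_series
  es <- data$expression_series
  want <- sort(unique(c(ts$time_min, if (100 %in% es$expression_pct) 30)))
  full <- simulate_pipette_force(p, variant, 100, max(want), dt = dt,
                                 times = want)
  sim_t <- full$force_nN[match(ts$time_min, full$time)]
  obj <- sum((sim_t - ts$force_nN)^2)
  for (k in seq_len(nrow(es))) {
    e <- es$expression_pct[k]
    sim_f <- if (e == 100) {
      full$force_nN[match(30, full$time)]
    } else {
      f <- simulate_pipette_force(p, variant, e, 30, dt = dt, times = 30)
      f$force_nN[match(30, f$time)]
    }
    obj <- obj + (sim_f - es$force_nN_at_30min[k])^2
  }
  obj
}

#' Fit the two-cell kinetic rates to dual-pipette data
#'
#' Multi-start Nelder-Mead minimization of [pipette_objective()] over the
#' four rates identifiable from two-cell data (`rho_u`, `nu_n`, `nu_p`,
#' `rho_c`). Starts are drawn log-uniformly from `[1e-6, 1e6]`; the search
#' runs in log10 space (rates are positive and span orders of magnitude)
#' and the best start is polished with a longer Nelder-Mead run.
#'
#' @param data a [pipette_dataset()].
#' @param variant model variant name.
#' @param n_restarts number of random starts (>= 1).
#' @param params base [kinetic_params()] supplying `rho_d` and `gamma`.
#' @param dt pathway step for the fitting simulations, min.
#' @param maxit Nelder-Mead iterations per start.
#' @param n_polish how many of the leading candidates to re-polish.
#' @param polish_maxit Nelder-Mead iterations per polish run.
#' @return List with `params` (fitted [kinetic_params()]), `objective`,
#'   and `restarts` (data.frame of per-start results).
#' @export
fit_kinetics <- function(data, variant, n_restarts = 40,
                         params = kinetic_params(), dt = 0.02,
                         maxit = 300, n_polish = 3, polish_maxit = 2000) {
  stopifnot(inherits(data, "pipette_dataset"))
  if (n_restarts < 1) stop("need at least one restart")
  objective <- make_pipette_objective(data, variant, params, dt)
  obj_log <- function(lp) objective(10^lp)
  starts <- matrix(runif(4 * n_restarts, -6, 6), ncol = 4)
  rows <- vector("list", nrow(starts))
  fits <- vector("list", nrow(starts))
  for (k in seq_len(nrow(starts))) {
    fit <- optim(starts[k, ], obj_log, method = "Nelder-Mead",
                 control = list(maxit = maxit, reltol = 1e-10))
    fits[[k]] <- fit
    rows[[k]] <- data.frame(restart = k, objective = fit$value,
                            rho_u = 10^fit$par[1], nu_n = 10^fit$par[2],
                            nu_p = 10^fit$par[3], rho_c = 10^fit$par[4])
  }
  # polish the leading candidates at full accuracy
  ord <- order(vapply(fits, `[[`, numeric(1), "value"))
  best <- NULL
  for (k in ord[seq_len(min(n_polish, length(ord)))]) {
    fit <- optim(fits[[k]]$par, obj_log, method = "Nelder-Mead",
                 control = list(maxit = polish_maxit, reltol = 1e-14))
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  r <- 10^best$par
  list(params = kinetic_params(rho_u = r[1], nu_n = r[2], nu_p = r[3],
                               rho_c = r[4], rho_d = params$rho_d,
                               gamma = params$gamma),
       objective = best$value,
       restarts = do.call(rbind, rows))
}

#' Per-site forces of the three-cell scenarios
#'
#' Runs one of the three-cell scenarios and extracts the separation-force
#' time courses at the centre cell's two contact sites.
#'
#' @param params [kinetic_params()].
#' @param variant model variant name.
#' @param staggered if `TRUE` the second neighbour arrives at 20 min;
#'   otherwise both neighbours are in contact from t = 0.
#' @param horizon simulated time, min.
#' @param dt pathway step, min.
#' @param resolution snapshot spacing of the force time courses, min.
#' @return data.frame with columns `time`, `force_A_nN`, `force_B_nN`
#'   (`force_B_nN` is `NA` before the second contact exists).
#' @export
three_cell_forces <- function(params, variant = "model2", staggered = FALSE,
                              horizon = 100, dt = 0.01, resolution = 1) {
  name <- if (staggered) "three_cell_staggered" else "three_cell_simultaneous"
  cfg <- make_scenario(name, variant = variant,
                       overrides = list(kinetic = params, duration = horizon,
                                        dt = dt,
                                        snapshot_interval = resolution))
  traj <- run_colony(cfg)
  centre <- 1L
  ids <- if (staggered) c(2L, 3L) else c(2L, 3L)
  out <- lapply(traj$snapshots, function(w) {
    con <- w$contacts
    pick <- function(j) {
      r <- which((con$cell_i == centre & con$cell_j == j) |
                   (con$cell_j == centre & con$cell_i == j))
      if (!length(r)) return(NA_real_)
      con$force_pN[r[1]] / 1000
    }
    data.frame(time = w$time, force_A_nN = pick(ids[1]),
               force_B_nN = pick(ids[2]))
  })
  do.call(rbind, out)
}

#' Time at which the centre cell's two contact forces equalize
#'
#' First snapshot time (after the second contact exists and carries force)
#' at which the two per-site separation forces agree within `tol` relative
#' to the larger one, in total simulated minutes.
#'
#' @param forces output of [three_cell_forces()].
#' @param tol relative tolerance.
#' @return Time in min (`NA` if never within the horizon).
#' @export
force_equalization_time <- function(forces, tol = 0.01) {
  ok <- !is.na(forces$force_B_nN) & pmax(forces$force_A_nN,
                                         forces$force_B_nN) > 0
  rel <- abs(forces$force_A_nN - forces$force_B_nN) /
    pmax(forces$force_A_nN, forces$force_B_nN, 1e-12)
  hit <- which(ok & rel <= tol)
  if (!length(hit)) return(NA_real_)
  forces$time[hit[1]]
}

#' Fit the inter-site redistribution rate
#'
#' One-dimensional fit of `gamma` against the two three-cell criteria: (a)
#' with both neighbours arriving simultaneously, each per-site force should
#' settle at half the two-cell force; and (b) with the second neighbour
#' arriving at 20 min, the two per-site forces should equalize (1%
#' relative) about `target_equalization` minutes later — the time frame
#' over which a fresh two-cell contact approaches its own steady state.
#' Criterion (b) identifies `gamma` (larger rates equalize sooner, smaller
#' rates later, `gamma = 0` never); criterion (a) is retained as a
#' consistency penalty. The search scans a log grid in `gamma` and refines
#' around the best value with [stats::optimize()].
#'
#' @param params [kinetic_params()] with the four two-cell rates fixed.
#' @param variant model variant name.
#' @param target_equalization target equalization delay after the second
#'   contact, min.
#' @param grid candidate `gamma` values for the coarse scan.
#' @param dt pathway step, min.
#' @param second_contact arrival time of the second neighbour, min.
#' @return List with `gamma` and `objective` (min^2-scale, with the
#'   half-force penalty in nN^2 added).
#' @export
fit_redistribution_rate <- function(params, variant = "model2",
                                    target_equalization = 30,
                                    grid = 10^seq(-2.5, 0.5, length.out = 13),
                                    dt = 0.02, second_contact = 20) {
  two <- simulate_pipette_force(params, variant, 100, 100, dt = dt,
                                times = 100)
  target_force <- two$force_nN[match(100, two$time)] / 2
  horizon <- second_contact + 4 * target_equalization
  objective <- function(gamma) {
    p <- modifyList(params, list(gamma = gamma))
    class(p) <- class(params)
    st <- three_cell_forces(p, variant, staggered = TRUE, horizon = horizon,
                            dt = dt, resolution = 0.5)
    teq <- force_equalization_time(st)
    if (is.na(teq)) teq <- horizon + target_equalization  # never equalized
    obj <- (teq - (second_contact + target_equalization))^2
    sim <- three_cell_forces(p, variant, staggered = FALSE, horizon = 100,
                             dt = dt, resolution = 100)
    last <- sim[nrow(sim), ]
    obj + (last$force_A_nN - target_force)^2 +
      (last$force_B_nN - target_force)^2
  }
  # two-stage deterministic grid search: the equalization-time readout is
  # piecewise constant, so golden-section refinement is not reliable
  vals <- vapply(grid, objective, numeric(1))
  k <- which.min(vals)
  lo <- log10(grid[max(1, k - 1)])
  hi <- log10(grid[min(length(grid), k + 1)])
  fine <- 10^seq(lo, hi, length.out = 11)
  fvals <- vapply(fine, objective, numeric(1))
  j <- which.min(fvals)
  if (fvals[j] <= vals[k]) {
    list(gamma = fine[j], objective = fvals[j])
  } else {
    list(gamma = grid[k], objective = vals[k])
  }
}
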