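# Colony-level read-outs used for model selection: cell counts, neighbour
# histograms, mean contact force, growth-law fits.

#' Neighbour-number histogram of a world
#'
#' A cell's neighbours are the cells it geometrically overlaps with
#' (overlap `h > 0`); M-phase sibling suppression is deliberately ignored
#' for counting. Growing epithelial layers show a characteristic histogram
#' with its mode at six neighbours, which healthy simulated colonies
#' reproduce.
#'
#' @param world a `colony_world`.
#' @return Named integer vector: count of cells per neighbour number
#'   (names `"0"`, `"1"`, ...); sums to the number of cells.
#' @examples
#' neighbour_histogram(make_hexagon_world())
#' @export
neighbour_histogram <- function(world) {
  cells <- world$cells
  n <- nrow(cells)
  if (n == 0) return(setNames(integer(0), character(0)))
  counts <- integer(n)
  if (n >= 2) {
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      d <- sqrt((cells$x[i] - cells$x[j])^2 + (cells$y[i] - cells$y[j])^2)
      if (d < cells$radius[i] + cells$radius[j]) {
        counts[i] <- counts[i] + 1L
        counts[j] <- counts[j] + 1L
      }
    }
  }
  tab <- table(factor(counts, levels = 0:max(counts)))
  setNames(as.integer(tab), names(tab))
}

#' Modal neighbour number
#'
#' @param world a `colony_world`.
#' @return The neighbour number with the highest cell count (smallest on
#'   ties).
#' @export
neighbour_mode <- function(world) {
  h <- neighbour_histogram(world)
  if (!length(h)) return(NA_integer_)
  as.integer(names(h)[which.max(h)])
}

#' Mean separation force over the contact sites of a world
#'
#' Arithmetic mean over all distinct attached contact pairs of the
#' bond-derived separation force `min(EBc_i, EBc_j) / anchor * 210 nN`
#' (anchor 15% for Model 1, 80% for Models 2/3). This is the
#' dual-pipette-comparable quantity: under Model 3 the force *acting*
#' inside the natural state is zero, but the separation force the bonds
#' would resist with is what colony tables report.
#'
#' @param world a `colony_world`.
#' @param variant model variant name.
#' @return Mean force, pN (0 if the world has no attached contacts).
#' @export
mean_contact_force <- function(world, variant) {
  variant <- check_variant(variant)
  con <- world$contacts
  con <- con[con$area > 0, , drop = FALSE]
  if (!nrow(con)) return(0)
  m <- pmin(con$EBc_i, con$EBc_j)
  mean(m / anchor_pct(variant) * FORCE_REF_PN)
}

#' Mean free E-cadherin of a world
#'
#' @param world a `colony_world`.
#' @return Mean cytosolic free E-cadherin over cells, %.
#' @export
mean_free_E <- function(world) {
  if (!nrow(world$cells)) return(NA_real_)
  mean(world$cells$E)
}

#' Summary metrics of one snapshot
#'
#' The read-outs used to evaluate colony runs: cell count, neighbour
#' histogram, mean separation force at the contact sites, mean free
#' E-cadherin and run status.
#'
#' @param world a `colony_world`.
#' @param variant model variant name.
#' @return List of class `colony_metrics`.
#' @export
colony_metrics <- function(world, variant) {
  structure(list(
    time = world$time,
    n_cells = nrow(world$cells),
    neighbour_histogram = neighbour_histogram(world),
    mean_contact_force = mean_contact_force(world, variant),
    mean_free_E = mean_free_E(world),
    status = world$status
  ), class = "colony_metrics")
}

#' @export
print.colony_metrics <- function(x, ...) {
  cat("t =", x$time, "min:", x$n_cells, "cells | mean force",
      round(x$mean_contact_force, 1), "pN | mean free E",
      round(x$mean_free_E, 1), "% |", x$status, "\n")
  cat("  neighbours:", paste(names(x$neighbour_histogram),
                             x$neighbour_histogram, sep = ":"), "\n")
  invisible(x)
}

#' Fit an exponential growth law to a cell-count series
#'
#' Least-squares fit of `log(count)` against time; colonies growing in
#' their exponential regime give a straight line whose slope is the growth
#' rate. The reference healthy-colony simulation grows at ~0.83 per day,
#' i.e. a doubling time of `ln 2 / 0.83` ~ 20 h.
#'
#' @param times times, days.
#' @param counts cell counts (>= 1).
#' @return List with `rate` (per day), `doubling_time` (hours) and the
#'   fitted `log_counts`.
#' @examples
#' fit_exponential_growth(0:7, 2 * exp(0.83 * (0:7)))
#' @export
fit_exponential_growth <- function(times, counts) {
  if (length(times) < 3) stop("need at least 3 time points")
  if (any(counts < 1)) stop("counts must be >= 1 (log fit)")
  fit <- lm(log(counts) ~ times)
  rate <- unname(coef(fit)[2])
  list(rate = rate,
       doubling_time = log(2) / rate * 24,
       log_counts = unname(fitted(fit)))
}
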