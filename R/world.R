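# World container: a snapshot of all cells plus the symmetric contact table.
#
# world$cells    data.frame: id, x, y, radius, expression, E, B, EB, phase,
#                phase_clock, rest_duration, arrested, sibling, pressure
# world$contacts data.frame: cell_i, cell_j (i < j), area, prev_area,
#                EBc_i (i's compartment facing j), EBc_j, force_pN
# world$time     min;  world$status  "running" | "collapsed" | "done"

#' Build a world from a table of cells
#'
#' Creates a `colony_world` from per-cell positions and (optionally) runs
#' the initial contact bookkeeping so overlapping pairs get contact sites.
#'
#' @param cells data.frame with at least `x` and `y`; missing columns are
#'   filled with defaults (`radius` 5 um, `expression` 100, pathway at the
#'   standard initial condition E = expression, B = 100, EB = 0).
#' @param time world clock, min.
#' @param bookkeep if `TRUE`, create contact sites for overlapping pairs.
#' @return A `colony_world`.
#' @examples
#' build_world(data.frame(x = c(0, 9.8), y = c(0, 0)))
#' @export
build_world <- function(cells, time = 0, bookkeep = TRUE) {
  n <- nrow(cells)
  defaults <- data.frame(
    id = seq_len(n), x = 0, y = 0, radius = 5, expression = 100,
    E = NA_real_, B = 100, EB = 0, phase = "REST", phase_clock = 0,
    rest_duration = NA_real_, arrested = FALSE, sibling = NA_integer_,
    pressure = 0
  )
  for (col in names(cells)) defaults[[col]] <- cells[[col]]
  defaults$E[is.na(defaults$E)] <- defaults$expression[is.na(defaults$E)]
  if (anyDuplicated(defaults$id)) stop("cell ids must be unique")
  world <- structure(list(cells = defaults, contacts = empty_contacts(),
                          time = time, status = "running"),
                     class = "colony_world")
  if (bookkeep) world <- contact_bookkeeping(world)
  world
}

empty_contacts <- function() {
  data.frame(cell_i = integer(), cell_j = integer(), area = numeric(),
             prev_area = numeric(), EBc_i = numeric(), EBc_j = numeric(),
             force_pN = numeric())
}

#' Update the contact-site table of a world
#'
#' For every geometrically overlapping, non-sibling pair a contact site
#' exists on both cells with the current intersection-disc area
#' (`prev_area` keeps the previous value); sites of separated pairs persist
#' with zero area while their compartments drain, and are removed (any
#' residual complexes returned to the cytosolic pool) once the bound level
#' falls below `drain_tol`.
#'
#' @param world a `colony_world`.
#' @param drain_tol bound-complex level below which a detached site is
#'   deleted, %.
#' @return The world with an updated contact table.
#' @export
contact_bookkeeping <- function(world, drain_tol = 1e-6) {
  cells <- world$cells
  n <- nrow(cells)
  con <- world$contacts
  con$prev_area <- con$area
  keyed <- paste(con$cell_i, con$cell_j)
  if (n >= 2) {
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      if (m_siblings(cells, i, j)) next
      d <- sqrt((cells$x[i] - cells$x[j])^2 + (cells$y[i] - cells$y[j])^2)
      geom <- contact_geometry(d, cells$radius[i], cells$radius[j])
      key <- paste(cells$id[i], cells$id[j])
      row <- match(key, keyed)
      if (geom$overlap > 0) {
        if (is.na(row)) {
          con <- rbind(con, data.frame(
            cell_i = cells$id[i], cell_j = cells$id[j],
            area = geom$contact_area, prev_area = 0,
            EBc_i = 0, EBc_j = 0, force_pN = 0))
          keyed <- c(keyed, key)
        } else {
          con$area[row] <- geom$contact_area
        }
      } else if (!is.na(row)) {
        con$area[row] <- 0
      }
    }
  }
  # sites whose partner vanished keep draining (area 0, a_d = 1); drop a
  # pair row only once every surviving side has drained below tolerance,
  # returning the residue to the surviving cytosol pools
  if (nrow(con)) {
    i_alive <- con$cell_i %in% cells$id
    j_alive <- con$cell_j %in% cells$id
    con$area[!(i_alive & j_alive)] <- 0
    drained <- con$area == 0 &
      (!i_alive | con$EBc_i < drain_tol) &
      (!j_alive | con$EBc_j < drain_tol)
    if (any(drained)) {
      for (r in which(drained)) {
        ii <- match(con$cell_i[r], cells$id)
        jj <- match(con$cell_j[r], cells$id)
        if (!is.na(ii)) cells$EB[ii] <- cells$EB[ii] + con$EBc_i[r]
        if (!is.na(jj)) cells$EB[jj] <- cells$EB[jj] + con$EBc_j[r]
      }
      con <- con[!drained, , drop = FALSE]
    }
    drop_dead <- !(con$cell_i %in% cells$id) & !(con$cell_j %in% cells$id)
    if (any(drop_dead)) con <- con[!drop_dead, , drop = FALSE]
  }
  world$cells <- cells
  world$contacts <- con
  world
}

m_siblings <- function(cells, i, j) {
  !is.na(cells$sibling[i]) && cells$sibling[i] == cells$id[j] &&
    cells$phase[i] == "M" && cells$phase[j] == "M"
}

#' Detect a collapsed configuration
#'
#' A world has collapsed when any non-sibling pair of cells is closer than
#' `frac` times the sum of their radii — cells so interpenetrated that they
#' can no longer be identified individually. Colony runs halt when this
#' triggers.
#'
#' @param world a `colony_world`.
#' @param frac collapse threshold as a fraction of `R_i + R_j`.
#' @return `TRUE` or `FALSE`.
#' @examples
#' detect_collapse(build_world(data.frame(x = c(0, 1), y = c(0, 0))))
#' @export
detect_collapse <- function(world, frac = 0.2) {
  cells <- world$cells
  n <- nrow(cells)
  if (n < 2) return(FALSE)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (m_siblings(cells, i, j)) next
    d <- sqrt((cells$x[i] - cells$x[j])^2 + (cells$y[i] - cells$y[j])^2)
    if (d < frac * (cells$radius[i] + cells$radius[j])) return(TRUE)
  }
  FALSE
}

#' Hexagonal test world
#'
#' A centre cell surrounded by six neighbours at the given spacing — the
#' configuration that defines the contact-inhibition pressure threshold
#' (six Hertz contacts at ~8.5 um sum to ~13 000 pN).
#'
#' @param spacing centre-to-neighbour distance, um.
#' @param radius cell radius, um.
#' @return A `colony_world` with 7 cells; cell 1 is the centre.
#' @examples
#' make_hexagon_world()
#' @export
make_hexagon_world <- function(spacing = 8.5, radius = 5) {
  ang <- seq(0, 5) * pi / 3
  build_world(data.frame(x = c(0, spacing * cos(ang)),
                         y = c(0, spacing * sin(ang)),
                         radius = radius))
}

#' @export
print.colony_world <- function(x, ...) {
  cat("<colony_world> t =", x$time, "min,", nrow(x$cells), "cells,",
      nrow(x$contacts), "contact pairs, status:", x$status, "\n")
  invisible(x)
}
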