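# File interfaces: YAML/JSON run configurations, CSV outputs, the JSON run
# manifest and dual-pipette CSV input.

#' Read a run configuration from YAML or JSON
#'
#' The file holds the [run_config()] arguments by name; nested parameter
#' blocks (`kinetic`, `mech`, `cycle`) are plain mappings, `cells` and
#' `introduce` are records/column maps. A configuration written with
#' [write_config()] reads back identically.
#'
#' @param path file path ending in `.yaml`, `.yml` or `.json`.
#' @return A `run_config`.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    yaml = , yml = yaml::read_yaml(path),
    json = jsonlite::fromJSON(path, simplifyVector = TRUE),
    stop("unsupported config format: .", ext)
  )
  config_from_list(raw)
}

config_from_list <- function(raw) {
  known <- names(formals(run_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown)) {
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  }
  for (fld in c("cells", "introduce")) {
    if (!is.null(raw[[fld]])) raw[[fld]] <- as.data.frame(raw[[fld]])
  }
  do.call(run_config, raw)
}

#' Write a run configuration to YAML or JSON
#'
#' @param config a `run_config`.
#' @param path destination ending in `.yaml`, `.yml` or `.json`.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  x <- config_as_list(config)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    yaml = , yml = yaml::write_yaml(x, path),
    json = jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                                null = "null", pretty = TRUE),
    stop("unsupported config format: .", ext)
  )
  invisible(path)
}

config_as_list <- function(config) {
  x <- unclass(config)
  x$kinetic <- unclass(x$kinetic)
  x$mech <- unclass(x$mech)
  x$cycle <- unclass(x$cycle)
  x[!vapply(x, is.null, logical(1))]
}

#' Write the CSV outputs and JSON manifest of a trajectory
#'
#' Writes four files into `dir`: `snapshots.csv` (one row per cell per
#' snapshot: `time_min`, `cell_id`, `x_um`, `y_um`, `radius_um`, `phase`,
#' `free_E_pct`, `free_B_pct`, `cyto_EB_pct`, `n_neighbours`,
#' `pressure_pN`), `contacts.csv` (`time_min`, `cell_i`, `cell_j`,
#' `area_um2`, `EBc_i_pct`, `EBc_j_pct`, `force_pN`), `metrics.csv` (one
#' row per snapshot) and `manifest.json` (configuration echo, seed, final
#' status, package version).
#'
#' @param trajectory a `colony_trajectory`.
#' @param dir output directory (created if missing).
#' @return Named character vector of the written paths, invisibly.
#' @export
write_outputs <- function(trajectory, dir) {
  stopifnot(inherits(trajectory, "colony_trajectory"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  snaps <- trajectory$snapshots
  snap_rows <- lapply(snaps, function(w) {
    cells <- w$cells
    if (!nrow(cells)) return(NULL)
    nb <- neighbour_counts(w)
    data.frame(time_min = w$time, cell_id = cells$id, x_um = cells$x,
               y_um = cells$y, radius_um = cells$radius,
               phase = cells$phase, free_E_pct = cells$E,
               free_B_pct = cells$B, cyto_EB_pct = cells$EB,
               n_neighbours = nb, pressure_pN = cells$pressure)
  })
  snap_df <- do.call(rbind, c(snap_rows, list(empty_snapshot_rows())))
  con_rows <- lapply(snaps, function(w) {
    con <- w$contacts
    if (!nrow(con)) return(NULL)
    data.frame(time_min = w$time, cell_i = con$cell_i, cell_j = con$cell_j,
               area_um2 = con$area, EBc_i_pct = con$EBc_i,
               EBc_j_pct = con$EBc_j, force_pN = con$force_pN)
  })
  con_df <- do.call(rbind, c(con_rows, list(empty_contact_rows())))
  paths <- c(snapshots = file.path(dir, "snapshots.csv"),
             contacts = file.path(dir, "contacts.csv"),
             metrics = file.path(dir, "metrics.csv"),
             manifest = file.path(dir, "manifest.json"))
  write.csv(snap_df, paths["snapshots"], row.names = FALSE)
  write.csv(con_df, paths["contacts"], row.names = FALSE)
  write.csv(trajectory$metrics, paths["metrics"], row.names = FALSE)
  manifest <- list(config = config_as_list(trajectory$config),
                   seed = trajectory$config$seed,
                   status = trajectory$status,
                   wall_time_s = trajectory$wall_time,
                   package_version =
                     as.character(utils::packageVersion("colonysim")))
  jsonlite::write_json(manifest, paths["manifest"], auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)
  invisible(paths)
}

empty_snapshot_rows <- function() {
  data.frame(time_min = numeric(), cell_id = integer(), x_um = numeric(),
             y_um = numeric(), radius_um = numeric(), phase = character(),
             free_E_pct = numeric(), free_B_pct = numeric(),
             cyto_EB_pct = numeric(), n_neighbours = integer(),
             pressure_pN = numeric())
}
empty_contact_rows <- function() {
  data.frame(time_min = numeric(), cell_i = integer(), cell_j = integer(),
             area_um2 = numeric(), EBc_i_pct = numeric(),
             EBc_j_pct = numeric(), force_pN = numeric())
}

neighbour_counts <- function(world) {
  cells <- world$cells
  n <- nrow(cells)
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
  counts
}

#' Read dual-pipette calibration CSVs
#'
#' @param time_path CSV with columns `time_min`, `force_nN`.
#' @param expression_path CSV with columns `expression_pct`,
#'   `force_nN_at_30min`.
#' @return A [pipette_dataset()].
#' @export
read_pipette_data <- function(time_path, expression_path) {
  pipette_dataset(read.csv(time_path), read.csv(expression_path))
}
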