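# Colony metrics, growth-law fitting, scenario builders, file round-trips.

test_that("neighbour histograms count geometric overlaps", {
  w <- build_world(data.frame(x = c(0, 9), y = c(0, 0)))
  expect_equal(neighbour_histogram(w), c("0" = 0, "1" = 2))
  # hexagon: the centre has 6 neighbours, each ring cell has centre + 2
  h <- neighbour_histogram(make_hexagon_world())
  expect_equal(h[["6"]], 1)
  expect_equal(h[["3"]], 6)
  expect_equal(neighbour_mode(make_hexagon_world()), 3)
  # total equals the cell count on random worlds
  set.seed(9)
  for (k in 1:10) {
    n <- sample(1:30, 1)
    w <- build_world(data.frame(x = runif(n, 0, 60), y = runif(n, 0, 60)))
    expect_equal(sum(neighbour_histogram(w)), n)
  }
})

test_that("mean contact force reports the bond-map separation force", {
  w <- build_world(data.frame(x = c(0, 9), y = c(0, 0)))
  expect_equal(mean_contact_force(w, "model2"), 0)  # uncharged contact
  w$contacts$EBc_i <- 80; w$contacts$EBc_j <- 80
  expect_equal(mean_contact_force(w, "model2"), 210000)
  expect_equal(mean_contact_force(w, "model1"), 80 / 15 * 210000)
  # invariant under relabeling
  w2 <- w
  w2$cells <- w2$cells[2:1, ]
  expect_equal(mean_contact_force(w2, "model2"),
               mean_contact_force(w, "model2"))
  # no contacts at all
  expect_equal(mean_contact_force(build_world(data.frame(x = 0, y = 0)),
                                  "model2"), 0)
})

test_that("exponential growth fits recover generating rates exactly", {
  times <- 0:7
  fit <- fit_exponential_growth(times, 2 * exp(0.83 * times))
  expect_equal(fit$rate, 0.83, tolerance = 1e-10)
  expect_equal(fit$doubling_time, log(2) / 0.83 * 24, tolerance = 1e-10)
  expect_equal(fit$doubling_time, 20, tolerance = 0.01)
  expect_equal(fit_exponential_growth(times, rep(7, 8))$rate, 0)
  expect_error(fit_exponential_growth(0:1, c(1, 2)), "at least 3")
  expect_error(fit_exponential_growth(times, rep(0, 8)), ">= 1")
})

test_that("named scenarios build the documented configurations", {
  two <- make_scenario("two_cell")
  expect_equal(nrow(two$cells), 2)
  expect_equal(two$duration, 100)
  expect_false(two$cycle_enabled)
  w <- build_world(two$cells)
  expect_equal(w$contacts$area, 1, tolerance = 1e-9)

  st <- make_scenario("three_cell_staggered")
  expect_equal(nrow(st$cells), 2)
  expect_equal(st$introduce$time, 20)

  col <- make_scenario("single_cell_colony")
  expect_equal(col$duration, 7 * 1440)
  expect_equal(col$forced_times, c(3, 7) * 1440)
  expect_null(col$cells)

  hexa <- make_scenario("hexagon_test")
  expect_equal(nrow(hexa$cells), 7)

  expect_error(make_scenario("warp_drive"))
  # overrides merge into the configuration
  o <- make_scenario("two_cell", overrides = list(duration = 5, seed = 9))
  expect_equal(o$duration, 5)
  expect_equal(o$seed, 9L)
})

test_that("configurations round-trip through YAML and JSON", {
  cfg <- make_scenario("two_cell", overrides = list(seed = 42, dt = 0.02))
  for (ext in c("yaml", "json")) {
    path <- file.path(tempdir(), paste0("cfg.", ext))
    write_config(cfg, path)
    back <- read_config(path)
    expect_equal(back$variant, cfg$variant)
    expect_equal(back$seed, cfg$seed)
    expect_equal(back$dt, cfg$dt)
    expect_equal(unclass(back$kinetic), unclass(cfg$kinetic))
    expect_equal(back$cells$x, cfg$cells$x)
    # a re-run from the round-tripped config reproduces the trajectory
  }
  bad <- file.path(tempdir(), "bad.json")
  jsonlite::write_json(list(variant = "model2", warp = 9), bad,
                       auto_unbox = TRUE)
  expect_error(read_config(bad), "unknown config keys")
  expect_error(read_config(file.path(tempdir(), "missing.yaml")), "not found")
})

test_that("trajectory outputs satisfy the row-count contracts", {
  traj <- run_colony(make_scenario("two_cell",
                                   overrides = list(duration = 10, dt = 0.02,
                                                    snapshot_interval = 5)))
  dir <- file.path(tempdir(), "out_test")
  paths <- write_outputs(traj, dir)
  expect_true(all(file.exists(paths)))
  snaps <- read.csv(paths[["snapshots"]])
  expect_equal(nrow(snaps),
               sum(vapply(traj$snapshots, function(w) nrow(w$cells),
                          numeric(1))))
  expect_equal(names(snaps),
               c("time_min", "cell_id", "x_um", "y_um", "radius_um", "phase",
                 "free_E_pct", "free_B_pct", "cyto_EB_pct", "n_neighbours",
                 "pressure_pN"))
  man <- jsonlite::fromJSON(paths[["manifest"]])
  expect_equal(man$seed, traj$config$seed)
  expect_equal(man$status, "done")
  # manifest config reproduces the run
  cfg2 <- colonysim:::config_from_list(man$config)
  traj2 <- run_colony(cfg2)
  expect_equal(snapshot_at(traj2)$cells$x, snapshot_at(traj)$cells$x)
})

test_that("pipette CSVs read back as a dataset", {
  tp <- file.path(tempdir(), "t.csv")
  ep <- file.path(tempdir(), "e.csv")
  write.csv(data.frame(time_min = c(5, 30), force_nN = c(50, 200)), tp,
            row.names = FALSE)
  write.csv(data.frame(expression_pct = 100, force_nN_at_30min = 200), ep,
            row.names = FALSE)
  d <- read_pipette_data(tp, ep)
  expect_s3_class(d, "pipette_dataset")
  expect_equal(nrow(d$time_series), 2)
})
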