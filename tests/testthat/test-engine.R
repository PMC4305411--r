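# Orchestration: bookkeeping, operator splitting, determinism, collapse.

test_that("contact bookkeeping creates, updates and drains sites symmetrically", {
  w <- build_world(data.frame(x = c(0, 9.8, 30), y = c(0, 0, 0)))
  expect_equal(nrow(w$contacts), 1)
  expect_equal(w$contacts$area, contact_geometry(9.8, 5, 5)$contact_area)
  expect_equal(w$contacts$prev_area, 0)   # de novo site

  # update keeps the previous area
  w$cells$x[2] <- 9.5
  w <- contact_bookkeeping(w)
  expect_equal(w$contacts$prev_area, contact_geometry(9.8, 5, 5)$contact_area)
  expect_equal(w$contacts$area, contact_geometry(9.5, 5, 5)$contact_area)

  # separation: the site persists while charged, then drains away
  w$contacts$EBc_i <- 5
  w$cells$x[2] <- 20
  w <- contact_bookkeeping(w)
  expect_equal(nrow(w$contacts), 1)
  expect_equal(w$contacts$area, 0)
  w$contacts$EBc_i <- 1e-9
  EB_before <- w$cells$EB[1]
  w <- contact_bookkeeping(w)
  expect_equal(nrow(w$contacts), 0)
  expect_equal(w$cells$EB[1], EB_before + 1e-9)  # residue returned

  # M-phase siblings get no mutual site
  w <- build_world(data.frame(x = c(0, 5), y = c(0, 0), radius = 3.969,
                              phase = "M", sibling = c(2L, 1L)))
  expect_equal(nrow(w$contacts), 0)
})

test_that("collapse detection flags interpenetrating non-sibling pairs", {
  expect_true(detect_collapse(build_world(data.frame(x = c(0, 1), y = c(0, 0)))))
  expect_false(detect_collapse(make_hexagon_world()))
  expect_false(detect_collapse(build_world(data.frame(x = 0, y = 0))))
  # dumb-bell partners are exempt during M
  w <- build_world(data.frame(x = c(0, 1), y = c(0, 0), radius = 3.969,
                              phase = "M", sibling = c(2L, 1L)))
  expect_false(detect_collapse(w))
})

test_that("runs are deterministic in (config, seed) and diverge across seeds", {
  cfg <- function(s) make_scenario("single_cell_colony", variant = "model3",
    overrides = list(duration = 1.2 * 1440, seed = s,
                     kinetic = kinetic_params(rho_d = 0.6)))
  a <- run_colony(cfg(3))
  b <- run_colony(cfg(3))
  expect_identical(a$metrics[, names(a$metrics) != "status"],
                   b$metrics[, names(b$metrics) != "status"])
  expect_identical(snapshot_at(a)$cells, snapshot_at(b)$cells)
  c <- run_colony(cfg(4))
  # different seeds draw different cycle phases/division times
  expect_false(identical(snapshot_at(a)$cells$x, snapshot_at(c)$cells$x))
})

test_that("a zero-duration run yields the single initial snapshot", {
  cfg <- make_scenario("two_cell", overrides = list(duration = 0))
  traj <- run_colony(cfg)
  expect_equal(length(traj$snapshots), 1)
  expect_equal(traj$snapshots[[1]]$time, 0)
  expect_equal(nrow(traj$snapshots[[1]]$cells), 2)
})

test_that("the compiled engine matches a monolithic R reference integration", {
  # same operator splitting assembled from the exported R operations
  ref <- reference_two_cell_run(20, dt = 0.02)
  cfg <- make_scenario("two_cell",
                       overrides = list(duration = 20, dt = 0.02,
                                        snapshot_interval = 0,
                                        forced_times = 20))
  eng <- snapshot_at(run_colony(cfg), 20)
  expect_equal(pair_force_nN(eng), pair_force_nN(ref), tolerance = 0.01)
  d_eng <- abs(diff(eng$cells$x))
  d_ref <- abs(diff(ref$cells$x))
  expect_equal(d_eng, d_ref, tolerance = 0.01)
  expect_equal(sort(eng$cells$EB), sort(ref$cells$EB), tolerance = 0.01)
})

test_that("staggered scenarios introduce the second neighbour on schedule", {
  cfg <- make_scenario("three_cell_staggered",
                       overrides = list(duration = 25, dt = 0.02))
  traj <- run_colony(cfg)
  n_at <- vapply(traj$snapshots, function(w) nrow(w$cells), numeric(1))
  times <- vapply(traj$snapshots, `[[`, numeric(1), "time")
  expect_true(all(n_at[times < 20] == 2))
  expect_true(all(n_at[times >= 20.5] == 3))
  # placed in contact with the centre cell (1 um^2 initial overlap, then
  # free to evolve): at its first snapshot the newcomer touches cell 1
  w <- snapshot_at(traj, 21)
  i1 <- match(1L, w$cells$id)
  i3 <- match(3L, w$cells$id)
  d13 <- sqrt((w$cells$x[i1] - w$cells$x[i3])^2 +
                (w$cells$y[i1] - w$cells$y[i3])^2)
  expect_lt(d13, w$cells$radius[i1] + w$cells$radius[i3] + 0.5)
})

test_that("conservation holds per cell across a dividing colony run", {
  traj <- colony_run("model3", 0.6, ci = TRUE, days = 2, seed = 5,
                     snapshot_interval = 720)
  for (w in traj$snapshots) {
    res <- conservation_residuals(w)
    expect_lt(max(abs(res)), 1e-6)
  }
  expect_equal(traj$status, "done")
})

test_that("forced evaluation snapshots land exactly on their times", {
  cfg <- make_scenario("single_cell_colony", variant = "model3",
    overrides = list(duration = 2 * 1440, snapshot_interval = 0,
                     forced_times = c(1000, 2000), seed = 2))
  traj <- run_colony(cfg)
  times <- vapply(traj$snapshots, `[[`, numeric(1), "time")
  expect_true(all(c(1000, 2000, 2880) %in% times))
})
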