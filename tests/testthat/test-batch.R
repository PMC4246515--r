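write_meas_file <- function(df, ext = ".csv") {
  path <- tempfile(fileext = ext)
  readr::write_csv(df, path, progress = FALSE)
  path
}

test_that("clean long-format tables read into validated series", {
  sim <- simulate_experiment(n = c(3, 0), seed = 2)
  sim <- sim[sim$group == "control", ]
  path <- write_meas_file(sim)
  tab <- read_measurements(path, mode = "growth")
  expect_equal(dplyr::n_distinct(tab$leaf_id), 3)
  expect_equal(nrow(tab), nrow(sim))
  expect_equal(attr(tab, "mode"), "growth")
  expect_equal(nrow(attr(tab, "rejected")), 0)
})

test_that("invalid rows are rejected with reasons, series kept if viable", {
  sim <- simulate_leaf_series(ctrl_params(), t = daily_schedule(),
                              sd = 2, seed = 1)
  bad <- sim
  bad$length[3] <- -5
  path <- write_meas_file(bad)
  expect_message(tab <- read_measurements(path, mode = "growth"),
                 "negative")
  expect_equal(nrow(tab), nrow(sim) - 1)
  expect_equal(nrow(attr(tab, "rejected")), 1)
})

test_that("duplicate abscissa invalidates the series", {
  sim <- simulate_leaf_series(ctrl_params(), t = daily_schedule())
  dup <- rbind(sim, sim[4, ])
  path <- write_meas_file(dup)
  expect_error(
    suppressMessages(read_measurements(path, mode = "growth")),
    "no valid measurements")
  # with a second clean leaf the batch survives, the dup series is dropped
  two <- rbind(dup,
               simulate_leaf_series(ctrl_params(), t = daily_schedule(),
                                    leaf_id = "leaf2"))
  path2 <- write_meas_file(two)
  expect_message(tab <- read_measurements(path2, mode = "growth"),
                 "duplicate")
  expect_equal(unique(tab$leaf_id), "leaf2")
})

test_that("missing columns and missing files are reported", {
  path <- write_meas_file(data.frame(x = 1:3))
  expect_error(read_measurements(path, mode = "growth"),
               "missing columns")
  expect_error(read_measurements(tempfile(), mode = "growth"),
               "not found")
})

test_that("wide sheets convert to the long format", {
  wide <- data.frame(leaf_id = c("a", "b"), group = "g",
                     `0` = c(0, 0), `14` = c(10, 12), `28` = c(30, 31),
                     check.names = FALSE)
  long <- wide_to_long(wide)
  expect_equal(nrow(long), 6)
  expect_setequal(unique(long$t), c(0, 14, 28))
})

test_that("run_batch conserves rows and recovers cohort parameters", {
  exp <- simulate_experiment(seed = 1)  # 9 control + 11 transgenic
  res <- suppressMessages(run_batch(exp, mode = "growth"))
  expect_equal(nrow(res), 20)
  expect_setequal(res$leaf_id, unique(exp$leaf_id))
  expect_true(all(res$converged))
  ctrl_mean <- mean(res$Lm[res$group == "control"])
  expect_equal(ctrl_mean, 535, tolerance = 0.02)
})

test_that("a failing series is flagged without aborting the batch", {
  exp <- simulate_experiment(n = c(4, 0), seed = 3)
  exp <- exp[exp$group == "control", ]
  flat <- tibble::tibble(leaf_id = "flat", group = "control",
                         t = daily_schedule(), length = 50)
  both <- rbind(exp, flat)
  res <- suppressMessages(run_batch(both, mode = "growth"))
  expect_equal(nrow(res), 5)
  expect_equal(sum(res$converged), 4)
  expect_match(res$error[res$leaf_id == "flat"], "degenerate")
})

test_that("batch runs are deterministic down to the written bytes", {
  exp <- simulate_experiment(n = c(4, 4), seed = 6)
  res1 <- suppressMessages(run_batch(exp, mode = "growth"))
  res2 <- suppressMessages(run_batch(exp, mode = "growth"))
  expect_identical(res1, res2)
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  write_results(res1, f1); write_results(res2, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("results survive a write/read round trip at full precision", {
  exp <- simulate_experiment(n = c(3, 0), seed = 4)
  res <- suppressMessages(run_batch(exp[exp$group == "control", ]))
  path <- tempfile(fileext = ".csv")
  write_results(res, path)
  back <- readr::read_csv(path, show_col_types = FALSE)
  expect_equal(nrow(back), nrow(res))
  for (cl in c("Lm", "tm", "te", "lermax", "t50pct")) {
    expect_equal(back[[cl]], res[[cl]], tolerance = 1e-6)
  }
  expect_error(write_results(res[0, ], tempfile(fileext = ".csv")),
               "empty")
})

test_that("cells-mode batch fits profiles and reports zones", {
  cells <- dplyr::bind_rows(lapply(1:3, function(i) {
    simulate_cell_profile(ctrl_cells(), p = seq(0.5, 60, by = 0.5),
                          cv = 0.2, seed = i,
                          leaf_id = sprintf("cell%02d", i))
  }))
  res <- suppressMessages(run_batch(cells, mode = "cells"))
  expect_equal(nrow(res), 3)
  expect_true(all(res$converged))
  expect_true(all(res$division_zone > 5 & res$division_zone < 30))
  expect_equal(res$division_zone + res$elongation_zone, res$Pe)
})

test_that("pooled fitting collapses replicates into one series per group", {
  exp <- simulate_experiment(n = c(4, 4), seed = 8)
  res <- suppressMessages(run_batch(exp, mode = "growth", pool = TRUE))
  expect_equal(nrow(res), 2)
  expect_setequal(res$leaf_id, c("control", "transgenic"))
  expect_true(all(res$converged))
})

test_that("day-recorded measurements convert through a temperature log", {
  p <- ctrl_params()
  days <- 0:17
  # sowing day accrues nothing; every later day adds 14 degree-days
  log <- data.frame(day = days, mean_temp = c(10, rep(24, 17)))
  sim <- simulate_leaf_series(p, t = days * 14, sd = 2, seed = 10)
  sim$day <- days
  sim$t <- NULL
  res <- suppressMessages(
    run_batch(sim, mode = "growth", temp_log = log, base_temp = 10))
  expect_true(res$converged)
  expect_equal(res$Lm, 535, tolerance = 0.03)
})
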