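test_that("rmse matches hand-computed values and checks its contract", {
  expect_equal(rmse(c(70, 70), c(70, 70)), 0)
  expect_equal(rmse(c(60, 80), c(70, 70)), 10)
  expect_equal(rmse(c(1, 2, 3), c(2, 2, 2)), sqrt(2 / 3))
  expect_error(rmse(1:3, 1:2), class = "binimpute_contract_error")
  expect_error(rmse(c(1, NA), c(1, 2)), class = "binimpute_contract_error")
})

test_that("evaluate_day with si equals a brute-force cross-day mean", {
  g <- generate_heart_like(synthetic_config(n_days = 8L, seed = 6L))
  gap <- gap_spec("03:22", 5, target_day = 3L)
  rec <- evaluate_day(g$grid, gap, "si", 5)
  slots <- gap_slots(g$grid, gap)
  truth <- g$grid$values[3L, slots]
  pred <- colMeans(g$grid$values[-3L, slots, drop = FALSE])
  expect_equal(rec$rmse, sqrt(mean((truth - pred)^2)), tolerance = 1e-12)
  # the input grid is left untouched
  expect_false(any(g$grid$missing_mask))
})

test_that("si scores zero when the target day equals the cross-day mean", {
  vals <- matrix(rep(c(60, 70, 80), times = 10L), 3L, 10L)
  vals <- rbind(vals, colMeans(vals))
  grid <- binimpute:::new_daygrid(as.Date("2023-01-01") + 0:3,
                                  (0:9) * 8640, 8640, vals,
                                  matrix(FALSE, 4L, 10L))
  gap <- gap_spec(2 * 8640, 8640 / 60, target_day = 4L)
  expect_equal(evaluate_day(grid, gap, "si", 3 * 8640 / 60)$rmse, 0)
})

test_that("a 24-h bin reproduces the no-binning baseline record", {
  g <- generate_heart_like(synthetic_config(n_days = 6L, seed = 6L))
  gap <- gap_spec("03:22", 5, target_day = 2L)
  full <- evaluate_day(g$grid, gap, "si", 1440)
  s <- sweep_bins(g$grid, "03:22", 5, algorithms = "si", bin_minutes = 15)
  base <- s$records[s$records$bin_size_minutes == 1440 &
                      s$records$day == g$grid$day_labels[2L], ]
  expect_equal(base$rmse, full$rmse, tolerance = 1e-12)
})

test_that("sweep_bins covers the full design and composes evaluate_day", {
  g <- generate_heart_like(synthetic_config(n_days = 5L, seed = 8L))
  s <- sweep_bins(g$grid, "03:22", 5, algorithms = c("si", "knn"),
                  bin_minutes = c(5, 15), params = list(k = 3L))
  # 5 days x 2 algorithms x (2 bins + baseline)
  expect_equal(nrow(s$records), 5L * 2L * 3L)
  expect_equal(nrow(unique(s$records[, c("day", "algorithm",
                                         "bin_size_minutes")])),
               nrow(s$records))
  one <- evaluate_day(g$grid, gap_spec("03:22", 5, 4L), "knn", 15,
                      params = list(k = 3L))
  got <- s$records[s$records$day == one$day & s$records$algorithm == "knn" &
                     s$records$bin_size_minutes == 15, ]
  expect_equal(got$rmse, one$rmse, tolerance = 1e-12)
})

fake_sweep <- function(binned, baseline, algorithm = "em", bin = 60) {
  days <- as.Date("2023-01-01") + seq_along(binned) - 1L
  rec <- rbind(
    data.frame(day = days, algorithm = algorithm, bin_size_minutes = bin,
               gap_start = "03:22", gap_span_minutes = 5, rmse = binned),
    data.frame(day = days, algorithm = algorithm, bin_size_minutes = 1440,
               gap_start = "03:22", gap_span_minutes = 5, rmse = baseline))
  structure(list(records = rec, baseline_bin = 1440),
            class = "sweep_result")
}

test_that("days_improved counts strict improvements only", {
  expect_equal(days_improved(fake_sweep(c(1, 2, 3), c(2, 2, 4)), "em", 60), 2)
  expect_equal(days_improved(fake_sweep(c(2, 2), c(2, 2)), "em", 60), 0)
  expect_equal(days_improved(fake_sweep(c(1, 1, 1), c(2, 3, 4)), "em", 60), 3)
  expect_error(days_improved(fake_sweep(1:3, c(2, 2, 4)), "si", 60),
               class = "binimpute_contract_error")
  # anti-monotone under inflating the binned scores
  s <- fake_sweep(c(1.1, 1.9, 2.5, 0.4), c(2, 2, 2, 2))
  s_up <- s
  s_up$records$rmse[s_up$records$bin_size_minutes == 60] <-
    s$records$rmse[s$records$bin_size_minutes == 60] + 0.5
  expect_lte(days_improved(s_up, "em", 60), days_improved(s, "em", 60))
})

test_that("days_improved_table summarizes every algorithm-bin pair", {
  g <- generate_heart_like(synthetic_config(n_days = 5L, seed = 8L))
  s <- sweep_bins(g$grid, "03:22", 5, algorithms = c("si", "em"),
                  bin_minutes = c(5, 60))
  tab <- days_improved_table(s)
  expect_equal(nrow(tab), 4L)
  expect_true(all(tab$days_improved >= 0 & tab$days_improved <= 5))
  expect_true(all(tab$n_days == 5L))
})

test_that("fluctuation is the sample SD of the day's window", {
  vals <- matrix(c(60, 70, 65, 65), 2L, 2L)
  grid <- binimpute:::new_daygrid(as.Date("2023-01-01") + 0:1,
                                  c(0, 43200), 43200, vals,
                                  matrix(FALSE, 2L, 2L))
  w <- structure(list(bin_minutes = 1440, first_slot = 1L, last_slot = 2L),
                 class = "bin_window")
  expect_equal(fluctuation(grid, w, 1L), sd(c(60, 65)))
  expect_equal(fluctuation(grid, w, 1L), 3.5355, tolerance = 1e-4)
  expect_equal(fluctuation(grid, w, 2L), sd(c(70, 65)))
  # translation invariance
  grid2 <- grid; grid2$values <- grid$values + 100
  expect_equal(fluctuation(grid2, w, 1L), fluctuation(grid, w, 1L))
  # constant window
  grid3 <- grid; grid3$values[1L, ] <- 42
  expect_equal(fluctuation(grid3, w, 1L), 0)
  # too few observed cells
  grid4 <- grid; grid4$missing_mask[1L, 2L] <- TRUE
  expect_error(fluctuation(grid4, w, 1L),
               class = "binimpute_contract_error")
})

test_that("fluctuation_split partitions all days", {
  g <- generate_heart_like(synthetic_config(n_days = 6L, seed = 2L))
  s <- sweep_bins(g$grid, "03:22", 5, algorithms = "si", bin_minutes = 15)
  fs <- fluctuation_split(s, g$grid, gap_spec("03:22", 5), "si", 15)
  expect_equal(length(fs$improved) + length(fs$not_improved), 6L)
  expect_true(all(c(fs$improved, fs$not_improved) >= 0))
  # forcing all days to improve empties the second sample
  s2 <- s
  s2$records$rmse[s2$records$bin_size_minutes == 1440] <- 1e9
  fs2 <- fluctuation_split(s2, g$grid, gap_spec("03:22", 5), "si", 15)
  expect_length(fs2$not_improved, 0L)
  expect_length(fs2$improved, 6L)
})

test_that("sweep results round-trip through the CSV schema", {
  g <- generate_heart_like(synthetic_config(n_days = 4L, seed = 3L))
  s <- sweep_bins(g$grid, "03:22", 5, algorithms = "si", bin_minutes = 10)
  p <- tempfile(fileext = ".csv")
  write_sweep_csv(s, p)
  s2 <- read_sweep_csv(p)
  expect_equal(s2$baseline_bin, s$baseline_bin)
  expect_equal(s2$records$rmse, s$records$rmse, tolerance = 1e-12)
  expect_equal(s2$records$day, s$records$day)
  expect_equal(days_improved_table(s2), days_improved_table(s))
})
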