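test_that("benchmark tables load with validated, monotone percentile scores", {
  med <- medicare_crc()
  expect_equal(unname(med$scores), c(67, 74, 78, 80, 83))
  expect_equal(names(med$scores), c("25", "50", "66", "75", "90"))

  ca <- ca_bp()
  expect_equal(unname(ca$scores), c(57, 65, 66, 68, 76))

  # all nine available rows load, and every one is non-decreasing
  tabs <- all_tables()
  expect_length(tabs, 9L)
  for (t in tabs) {
    expect_false(is.unsorted(t$scores), info = paste(t$measure_id, t$segment))
    expect_true(all(t$scores >= 0 & t$scores <= 100))
  }
})

test_that("unavailable measure/segment pairs raise an explicit condition", {
  expect_error(load_benchmark_table(bench_csv, "crc_screening", "Medicaid"),
               class = "qi_data_unavailable")
  expect_error(load_benchmark_table(bench_csv, "crc_screening", "Atlantis"),
               class = "qi_data_unavailable")
  # and the bulk loader just skips them instead of zero-filling
  expect_null(all_tables()[["crc_screening.Medicaid"]])
})

test_that("invalid score vectors are rejected at construction", {
  expect_error(benchmark_table("m", "s", c(70, 68, 72, 75, 80)),
               class = "qi_validation_error")
  expect_error(benchmark_table("m", "s", c(10, 20, 30, 40, 110)),
               class = "qi_validation_error")
  expect_error(benchmark_table("m", "s", c(10, 20, 30)),
               class = "qi_validation_error")
})

test_that("make_bins partitions (0,100] with conservative assumed scores", {
  bins <- make_bins(medicare_crc(), "percentile_width")
  expect_equal(bins$population_weight, c(0.25, 0.25, 0.16, 0.09, 0.15, 0.10))
  expect_equal(bins$assumed_score, c(67, 74, 78, 80, 83, 83))
  expect_equal(bins$lower_percentile, c(0, 25, 50, 66, 75, 90))
  expect_equal(bins$upper_percentile, c(25, 50, 66, 75, 90, 100))

  eq <- make_bins(medicare_crc(), "equal_bins")
  expect_equal(eq$population_weight, rep(1 / 6, 6))

  # degenerate constant distribution: every bin assumes the same score
  flat <- benchmark_table("m", "s", rep(70, 5))
  expect_equal(make_bins(flat)$assumed_score, rep(70, 6))

  expect_error(make_bins(medicare_crc(), "bogus"))
})

test_that("bin weights sum to one for every table under both rules", {
  for (t in all_tables()) {
    for (rule in c("percentile_width", "equal_bins")) {
      expect_equal(sum(make_bins(t, rule)$population_weight), 1,
                   tolerance = 1e-12)
    }
  }
})

test_that("improvement_gap is the non-negative shortfall to the target", {
  expect_equal(improvement_gap(57, 66), 9)
  expect_equal(improvement_gap(78, 66), 0)
  expect_equal(improvement_gap(66, 66), 0)
  # monotone: non-decreasing in target, non-increasing in assumed score
  scores <- seq(0, 100, by = 7)
  for (target in c(30, 66, 90)) {
    gaps <- improvement_gap(scores, target)
    expect_true(all(diff(gaps) <= 0))
    expect_true(all(improvement_gap(scores, min(100, target + 10)) >= gaps))
  }
  expect_error(improvement_gap(50, 150), class = "qi_validation_error")
})

test_that("conservative bin assignment never understates a plan's score", {
  tab <- ca_bp()
  set.seed(42)
  scores <- runif(500, 0, 100)
  assumed <- assume_bin_score(scores, tab)
  p90 <- unname(tab$scores["90"])
  below <- scores <= p90
  expect_true(all(assumed[below] >= scores[below]))
  # hence the assumed improvement gap never exceeds the true gap
  for (target in unname(tab$scores[c("66", "90")])) {
    expect_true(all(improvement_gap(assumed, target) <=
                      improvement_gap(scores, target) + 1e-12))
  }
  # plans sitting exactly at a reported percentile keep their own score
  expect_equal(assume_bin_score(unname(tab$scores), tab),
               unname(tab$scores))
})
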