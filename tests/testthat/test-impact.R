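test_that("NNT is the reciprocal of deaths averted per 1000", {
  expect_identical(nnt_from_deaths_per_1000(27), 37)
  expect_identical(nnt_from_deaths_per_1000(1000), 1)
  expect_identical(nnt_from_deaths_per_1000(2), 500)
  # exact value available for downstream arithmetic
  expect_equal(nnt_from_deaths_per_1000(27, report_integer = FALSE), 1000 / 27)
  expect_error(nnt_from_deaths_per_1000(0), class = "qi_validation_error")
  expect_error(nnt_from_deaths_per_1000(-3), class = "qi_validation_error")
})

test_that("numerator gain sums weighted shortfalls over bins", {
  # nobody below the target: zero gain
  flat <- make_bins(benchmark_table("m", "s", c(80, 82, 84, 86, 88)))
  expect_equal(numerator_gain(flat, 66, 5e6), 0)

  # two hand-built bins: 0.5 * 1000 * 20 / 100
  bins <- tibble::tibble(assumed_score = c(40, 60),
                         population_weight = c(0.5, 0.5))
  expect_equal(numerator_gain(bins, 60, 1000), 100)

  # the California Marketplace bp distribution: 2.5pp of the denominator
  ca <- make_bins(ca_bp(), "percentile_width")
  expect_equal(numerator_gain(ca, 66, 555200), 13880)
})

test_that("lives saved respects the annualization mode", {
  models <- default_benefit_models()
  # lifetime: (gain / NNT) * horizon / remaining life expectancy
  expect_equal(lives_saved(20865, models$crc_screening, 10),
               20865 / 37 * 10 / 22)
  expect_equal(lives_saved(20865, models$crc_screening, 10), 257,
               tolerance = 0.01)
  expect_equal(lives_saved(0, models$crc_screening), 0)
  # trial: (gain / NNT) * horizon / follow-up
  expect_equal(lives_saved(1168105, models$bp_control, 10),
               1168105 / 101 * 10 / 4)
  # the two modes must not be interchangeable
  expect_error(benefit_model("x", 50, "lifetime", lifetime_years = 22,
                             trial_followup_years = 4),
               class = "qi_validation_error")
  expect_error(benefit_model("x", 50, "trial"), class = "qi_validation_error")
})

test_that("events averted use the event NNT or are absent", {
  models <- default_benefit_models()
  expect_equal(events_averted(4428717, models$bp_control, 10),
               4428717 / 80.72 * 10 / 4)
  expect_equal(events_averted(4428717, models$bp_control, 10), 137164,
               tolerance = 0.01)
  expect_equal(events_averted(0, models$bp_control), 0)
  expect_true(is.na(events_averted(1e6, models$crc_screening)))
})

test_that("national aggregation sums segments and spotlights California", {
  mk_row <- function(seg, lives) {
    tibble::tibble(measure = "crc_screening", segment = seg, scenario = "p66",
                   denominator = NA_real_, target_score = NA_real_,
                   numerator_gain = NA_real_, lives_saved = lives,
                   events_averted = NA_real_, annual_lives_saved = lives / 10)
  }
  rows <- rbind(mk_row("Medicare", 15127), mk_row("Marketplace", 2680),
                mk_row("Commercial", 15695))
  nat <- aggregate_national(rows)
  expect_equal(nat$lives_saved, 33502)
  expect_equal(nat$segment, "National")

  # California Marketplace never enters the national total
  with_ca <- rbind(rows, mk_row("CA-Marketplace", 257))
  expect_equal(aggregate_national(with_ca)$lives_saved, 33502)

  # single segment aggregates to itself
  expect_equal(aggregate_national(mk_row("Medicare", 15127))$lives_saved,
               15127)

  mixed <- rbind(rows, within(mk_row("Medicaid", 1), scenario <- "p90"))
  expect_error(aggregate_national(mixed), class = "qi_validation_error")
})

test_that("percent annual death reduction follows its defining formula", {
  expect_equal(round_half_up(
    percent_annual_death_reduction(110067, 10, 691095), 1), 1.6)
  expect_equal(percent_annual_death_reduction(280487, 10, 691095), 4.06,
               tolerance = 0.1)
  expect_equal(percent_annual_death_reduction(0, 10, 51869), 0)
  expect_error(percent_annual_death_reduction(100, 10, 0),
               class = "qi_validation_error")
})

test_that("benefit outputs are linear in gain, horizon, and denominator", {
  models <- default_benefit_models()
  tab <- medicare_crc()
  bins <- make_bins(tab)
  g1 <- numerator_gain(bins, 78, 1e6)
  expect_equal(numerator_gain(bins, 78, 2e6), 2 * g1)
  for (m in models) {
    expect_equal(lives_saved(2 * g1, m, 10), 2 * lives_saved(g1, m, 10))
    expect_equal(lives_saved(g1, m, 20), 2 * lives_saved(g1, m, 10))
  }
  expect_equal(events_averted(2 * g1, models$bp_control),
               2 * events_averted(g1, models$bp_control))
})

test_that("binned gain equals the plan-level oracle when plans sit at bin scores", {
  for (t in all_tables()) {
    for (rule in c("percentile_width", "equal_bins")) {
      bins <- make_bins(t, rule)
      target <- unname(t$scores["66"])
      engine <- numerator_gain(bins, target, 1e6)
      plans <- plans_at_bin_scores(t, rule, total = 1e6)
      # direct plan-by-plan sum with shares equal to the bin weights
      oracle <- plan_level_numerator_gain(
        plans, stats::setNames(pmax(plans$score, target), plans$plan_id),
        denominator = 1e6, share_rule = "by_enrollment")
      expect_equal(engine, oracle, tolerance = 1e-9)
    }
  }
})

test_that("reconcile_reported warns only on real discrepancies", {
  expect_warning(reconcile_reported(284160, 280487, "bp p90 national lives"),
                 class = "qi_reported_mismatch")
  expect_no_warning(r <- reconcile_reported(33429, 33502, "crc p66 lives"))
  expect_true(r$consistent)
})
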