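test_that("score generation is seeded, bounded, and reproducible", {
  tab <- load_benchmark_table(bench_csv, "crc_screening", "Marketplace")
  cfg <- synth_config(1000, tab, 1e6, seed = 1)
  s1 <- synth_plan_scores(cfg)
  s2 <- synth_plan_scores(cfg)
  expect_identical(s1, s2)
  expect_length(s1, 1000)
  expect_true(all(s1 >= 0 & s1 <= 100))

  tiny <- synth_plan_scores(synth_config(2, tab, 100, seed = 7))
  expect_length(tiny, 2)
  expect_true(all(tiny >= 0 & tiny <= 100))

  # different seeds give different rosters
  expect_false(identical(
    s1, synth_plan_scores(synth_config(1000, tab, 1e6, seed = 2))))

  # the generator draws privately: global RNG state is untouched
  set.seed(99); before <- .Random.seed
  invisible(synth_plan_scores(cfg))
  expect_identical(before, .Random.seed)
})

test_that("empirical percentiles of large rosters match the target table", {
  # Marketplace colorectal-screening distribution {47,55,61,63,69}
  tab <- load_benchmark_table(bench_csv, "crc_screening", "Marketplace")
  scores <- synth_plan_scores(synth_config(1000, tab, 1e6, seed = 1))
  p25 <- unname(stats::quantile(scores, 0.25))
  expect_gte(p25, 45)
  expect_lte(p25, 49)

  for (n in c(200, 1000)) {
    for (t in all_tables()) {
      s <- synth_plan_scores(synth_config(n, t, 1e6, seed = 11))
      emp <- stats::quantile(s, benchmark_percentiles / 100)
      expect_true(all(abs(emp - t$scores) <= 2),
                  info = sprintf("%s/%s n=%d", t$measure_id, t$segment, n))
    }
  }

  # infeasible (non-monotone) target tables are rejected up front
  expect_error(synth_config(10, c(60, 55, 50, 45, 40), 1e4),
               class = "qi_validation_error")
})

test_that("enrollment concentrates in the lowest performer and conserves totals", {
  tab <- ca_bp()
  cfg <- synth_config(10, tab, 1e6, enrollment_concentration = 0.33, seed = 3)
  roster <- synth_roster(cfg)
  expect_equal(roster$enrollment[which.min(roster$score)], 330000)
  expect_equal(sum(roster$enrollment), 1e6)

  # zero concentration: uniform split
  uni <- synth_roster(synth_config(8, tab, 800, seed = 3))
  expect_true(all(uni$enrollment == 100))

  # exact conservation survives awkward totals
  odd <- synth_roster(synth_config(7, tab, 1000003,
                                   enrollment_concentration = 0.1, seed = 5))
  expect_identical(sum(odd$enrollment), 1000003L)
})

test_that("synthetic populations apportion totals by largest remainder", {
  prof <- data.frame(age_lo = c(0, 50), age_hi = c(49, 75),
                     fraction = c(0.5, 0.5))
  pop <- synth_population("s", 100, prof)
  expect_equal(pop$bands$enrollment, c(50, 50))

  # 7 members over two equal halves: tie broken toward the first band
  pop7 <- synth_population("s", 7, prof)
  expect_equal(pop7$bands$enrollment, c(4, 3))
  expect_equal(pop7$total_enrollment, 7)

  # identity through the denominator computation
  single <- synth_population("Medicare", 61e6, data.frame(
    age_lo = 50, age_hi = 75, fraction = 1))
  expect_equal(eligible_denominator(single, measure_spec("crc_screening")),
               61e6)

  expect_error(synth_population("s", 10, data.frame(
    age_lo = 0, age_hi = 10, fraction = 0.7)),
    class = "qi_validation_error")
  expect_equal(largest_remainder(7, c(0.5, 0.5)), c(4L, 3L))
})

test_that("binned approximation is conservative on synthetic rosters", {
  tab <- ca_bp()
  p66 <- unname(tab$scores["66"])
  for (seed in 1:25) {
    roster <- synth_roster(synth_config(
      40, tab, 1e5, enrollment_concentration = 0.33, seed = seed))
    targets <- stats::setNames(pmax(roster$score, p66), roster$plan_id)
    exact <- plan_level_numerator_gain(roster, targets, 555200, "even")
    binned_roster <- roster
    binned_roster$score <- assume_bin_score(roster$score, tab)
    btargets <- stats::setNames(pmax(binned_roster$score, p66),
                                binned_roster$plan_id)
    binned <- plan_level_numerator_gain(binned_roster, btargets, 555200,
                                        "even")
    expect_lte(binned, exact + 1e-9)
  }
})
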