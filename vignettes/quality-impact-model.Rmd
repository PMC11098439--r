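---
title: "The quality-impact model: methods, assumptions, and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The quality-impact model: methods, assumptions, and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qualityimpact)
```

## The question the model answers

Value-based purchasing programs increasingly tie health-plan payment to
performance on a small set of clinical quality measures, with percentile
benchmarks as the accountability standard (most prominently, penalties for
plans below the 66th percentile). The natural question for a purchaser is:
if the lower-performing plans actually reached the benchmark, how many
lives would that save? This package answers it for two measures with
well-characterized mortality benefits: colorectal cancer screening among
50- to 75-year-olds, and blood pressure control (SBP < 140 and DBP < 90
mm Hg) among hypertensive adults.

## Model structure

The estimation chain is deliberately simple and auditable; each step is one
exported function.

### 1. Conservative percentile binning

Plan-level performance distributions are proprietary; what is public is the
measure score at the 25th, 50th, 66th, 75th and 90th percentiles of each
segment's plan distribution. `make_bins()` partitions percentile rank
(0, 100] at edges {0, 25, 50, 66, 75, 90, 100} and assumes every plan in a
bin already scores at the bin's upper reported percentile (the top bin
keeps the 90th-percentile score). This *next-highest-percentile* rule is
conservative: each plan's assumed improvement gap is a lower bound on its
true gap, so modelled benefits understate true benefits. The property is
exact at the plan level and is enforced by test against synthetic rosters
(`assume_bin_score()` never returns less than the true score below the
90th-percentile score).

Market share across bins follows one of two readings of "evenly
distributed" performance:

* `percentile_width` (default): share proportional to the percentile
  interval, weights {0.25, 0.25, 0.16, 0.09, 0.15, 0.10};
* `equal_bins`: one sixth per bin.

Both are implemented because neither reading reproduces every published
scenario ratio (see *Known non-reproductions*); the choice is a
configuration knob, not a fitted parameter.

### 2. Eligible denominators

`eligible_denominator()` computes each segment's measure-eligible
population from enrollment by closed integer age band: the 50–75 window for
screening, and an 18–85 window (the conventional adult denominator; the
window is configurable because no authoritative definition accompanies the
benchmark data) times age-specific hypertension prevalence for blood
pressure. Bands that straddle a window edge are prorated uniformly by years
of overlap, with a warning — no within-band age distribution is available,
and uniformity is the least-informative assumption. Managed-care benchmark
distributions are applied to full-population enrollment simply by supplying
full-population counts in the population table; no separate scaling factor
exists.

### 3. Numerator gain and benefit conversion

`numerator_gain()` is linear in the denominator and additive over bins.
`lives_saved()` applies a number needed to treat, with two annualization
modes that must never be conflated:

* **lifetime** (screening): the evidence base is a lifetime benefit — 27
  deaths averted per 1000 screened, NNT = 1000/27 ≈ 37 — spread over 22
  years of average remaining life expectancy after screening initiation at
  age 50. Decade lives = gain/NNT × 10/22.
* **trial** (blood pressure): the evidence base is an absolute risk
  reduction over a 4-year median trial follow-up, NNT 101; the
  per-follow-up benefit is assumed to repeat while improvement is
  sustained. Decade lives = gain/NNT × 10/4.

Conflating the two modes (dividing a trial-period benefit by remaining life
expectancy, or vice versa) is the single most consequential implementation
hazard in this model class, which is why the mode is an explicit, validated
field of `benefit_model()` rather than a formula convention.

The MACE event NNT for blood pressure (80.72) is a **calibrated constant**:
no printed trial value exists for the measure's composite endpoint, so the
shipped default is back-solved from the published national 66th-percentile
event total and labelled as such. Users with a preferred trial-derived
value can supply their own.

All internal arithmetic is real-valued; person counts and percentages are
rounded (half-up) only at the reporting layer.

### 4. Aggregation and summary statistics

`aggregate_national()` sums segments component-wise after verifying a
single measure and scenario; the California Marketplace is a spotlight
segment and never enters national totals.
`percent_annual_death_reduction()` divides annualized lives saved by annual
condition-specific deaths (51,869 colorectal cancer; 691,095 hypertension).
`table1_summary()` reports the global score extremes and each segment's
performance spread, defined here as the mean 90th-minus-25th-percentile
range over the segment's available measures, compared among segments
reporting both measures — this definition reproduces the expected ordering
(Marketplace widest, Medicare narrowest) without inventing per-measure
rankings the data cannot support.

## Sensitivity analyses

With a plan-level roster (`plan_id, segment, enrollment, score`), two
assumptions can be relaxed jointly:

* **Improvement depth**: `next_decile_targets()` moves each plan below the
  66th-percentile benchmark only to the upper score boundary of its next
  performance decile, capped at the benchmark. Deciles default to deciles
  of plans (enrollment-unweighted score ranks); an enrollment-weighted
  `members` basis is available because the convention is genuinely
  ambiguous — both are exposed rather than silently chosen.
* **Market share**: `plan_level_numerator_gain()` splits the segment
  denominator evenly across plans or proportionally to enrollment. The
  even/actual contrast matters exactly when enrollment concentrates in
  low performers; published concentration facts (33% of California
  Marketplace members in the lowest-performing hypertension plan, 16% for
  screening) motivate the synthetic generator's concentration knob.

`relative_change()` reports the variant-vs-baseline difference in percent.
The actual California roster is proprietary, so sensitivity validation is
property-based on synthetic rosters calibrated to the concentration facts,
not a reproduction of the published ±percent figures.

## The synthetic-data generator

`synth_plan_scores()` draws rosters by stratified inverse-transform
sampling from the monotone piecewise-linear quantile function through the
five reported percentile points, extended flat-ish to the endpoints with
±5-point tails clipped to [0, 100] (no tail information exists; the choice
only needs to preserve the five reported percentiles). Stratification (one
uniform per equal-probability stratum, in random plan order) bounds the
empirical-quantile error at O(1/n), so rosters of 200+ plans match their
target percentiles within 2 score points by construction, not just on
average. `synth_enrollment()` assigns a configurable fraction of members to
the lowest-scoring plan and splits the rest uniformly;
`synth_population()` spreads totals over age bands. All integer
apportionment uses largest-remainder rounding (ties to the first category),
so configured totals are conserved exactly. All randomness flows from the
single seed in `synth_config()`, drawn on a private RNG stream that leaves
the global random state untouched.

What the generator emulates: score distributions consistent with a
benchmark table, and enrollment concentration in low performers. What it
does not: actuarial enrollment structure, score–size correlation (larger
plans tend to perform better in reality), regional variation, or score
dynamics over time. Tests passing on synthetic rosters therefore validate
the *arithmetic and its invariants* — conservativeness, linearity,
conservation, calibration — not the realism of any particular market.

## Shipped fixtures and what the reference scenario validates

`inst/extdata/benchmarks_2019.csv` carries the 2019-measurement-year
percentile benchmark scores by measure and segment (Medicaid has no
colorectal-screening distribution; the pair is flagged "data unavailable",
never zero-filled). `population_synthetic.csv` and
`prevalence_synthetic.csv` are **synthetic**: the age-band construction
behind the published eligible populations is not publicly available, so the
fixture uses three adult bands (18–49, 50–75, 76–85), plausible
hypertension prevalence rates (0.20/0.60/0.75), and enrollments back-solved
so that the pipeline's 66th-percentile numerator gains reproduce the
published reference scenario exactly, while keeping segment totals at the
headline constants where feasible (61M Medicare, 169M commercial). Two
consequences are documented rather than hidden: the fixture does not
reproduce the published segment-level prevalence summaries (73% Medicare /
41% commercial), and downstream validation exercises the benefit-conversion
chain, aggregation, and distribution engine — not the original
enrollment-data assembly.

Problem sizes used in the shipped tests and acceptance script: rosters of
6–1000 plans, 100 seeds for the conservativeness property, all nine
benchmark rows for calibration and monotonicity checks. The full suite runs
in a few seconds on one CPU.

## Known non-reproductions

These residuals are logged as structured warnings by
`reconcile_reported()` and asserted as such in the tests; they are not
tuned away:

* The published blood-pressure 90th-percentile segment lives sum to
  284,160, but the published national total is 280,487 (~1.3%
  inconsistency). The package reports the sum.
* The percent-reduction formula gives 6.46% / 16.47% for colorectal
  screening at the 66th/90th percentiles, not the published 6.9% / 17.5%.
  The formula is implemented as defined and the residual reported.
* The Medicare and commercial colorectal p90:p66 lives ratios are not
  reproduced under either market-share weighting (e.g. Medicare: model
  ~1.95, published ~3.04), while the California Marketplace and Medicare
  hypertension ratios approximately are. The original even-distribution
  convention evidently differs in a way the public record does not pin
  down; both implemented conventions are reported per segment.

## Numerical choices and degenerate inputs

* Ties at a benchmark (assumed score equal to target) contribute zero gain.
* A constant benchmark table yields identical assumed scores in every bin
  and zero gain for targets at or below it.
* Bin weights must sum to 1 within 1e-9; age-profile and apportionment
  fractions likewise.
* Reported integer NNTs round half-up (1000/27 → 37); all downstream
  arithmetic can use the exact value.
* Empty scenario lists run successfully and produce empty, writable
  outputs; missing benchmark pairs raise `qi_data_unavailable` conditions
  that the pipeline converts to flagged rows.

## Limitations

Beyond the fixture caveats above: benefits are limited to deaths (and MACE
for blood pressure) — kidney failure, vision loss, nonfatal cancer outcomes
and spillover benefits to members outside the measure numerator are not
modelled; effect sizes are not segment-specific; national distributions
ignore regional variation; and the conservative binning plus
even-distribution assumptions bias in opposite directions, so the net bias
of any single estimate is unsigned.
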