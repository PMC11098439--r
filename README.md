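# qualityimpact

Estimates the population health benefits — lives saved and major
cardiovascular events averted — if US health plans improved their
performance on two widely used clinical quality measures: colorectal cancer
screening (members aged 50–75 screened per guidelines) and controlling high
blood pressure (hypertensive members with SBP < 140 and DBP < 90 mm Hg).
It is written for health-policy analysts evaluating value-based purchasing
programs that hold plans to percentile benchmarks, such as programs that
penalize plans performing below the 66th percentile.

## The model

Plan performance within a market segment (Medicare, Medicaid, Marketplace,
commercial, plus the California Marketplace as a spotlight segment) is known
only at five reported percentiles (25th, 50th, 66th, 75th, 90th). The model:

1. **Bins the distribution conservatively.** Plans between reported
   percentiles are assumed to already perform at the next highest reported
   percentile, with bin edges {0, 25, 50, 66, 75, 90, 100} and plan market
   share spread evenly over percentile rank (an equal-bins weighting is also
   available). This understates improvement gaps by construction.
2. **Computes the eligible denominator** per segment from enrollment by age
   band, times age-specific hypertension prevalence for the blood-pressure
   measure.
3. **Computes the numerator gain** when every bin below a target benchmark
   (66th or 90th percentile score) rises to it:
   `gain = Σ_bins weight × denominator × max(0, target − assumed score)/100`.
4. **Converts gains to benefits via number needed to treat (NNT).**
   Screening: 27 deaths averted per 1000 screened over a lifetime
   (NNT = 1000/27 ≈ 37), annualized over 22 years of remaining life
   expectancy: `lives = gain/NNT × horizon/22`. Blood pressure: NNT 101
   from the absolute risk reduction of a 4-year treatment meta-analysis:
   `lives = gain/NNT × horizon/4`; MACE averted use a calibrated event
   NNT of 80.72 on the same trial-period accrual.
5. **Aggregates** national totals (the California Marketplace is reported
   separately, never summed in) and expresses decade lives saved as a
   percent of annual condition-specific deaths (51,869 colorectal cancer;
   691,095 hypertension).

Sensitivity analyses replace the binned distribution with a plan-level
roster: each plan below the benchmark improves only to the next performance
decile, with the segment denominator split evenly across plans or in
proportion to actual enrollment. A seeded synthetic-roster generator
(stratified inverse-transform sampling from the piecewise-linear quantile
function through the five reported percentiles) makes every stage testable
without proprietary data.

## Worked example

```r
library(qualityimpact)

res <- run_pipeline(run_config())   # shipped fixtures, p66 and p90 scenarios
subset(res$national, scenario == "p66",
       select = c(measure, numerator_gain, lives_saved, events_averted))
#>         measure numerator_gain lives_saved events_averted
#>      bp_control        4428717   109621.71       137162.9
#>   crc_screening        2721095    33428.69             NA
```

Reading: raising every plan below its segment's 66th-percentile benchmark to
that benchmark moves about 4.43 million members into blood-pressure control
nationally, which sustained over a decade saves about 109,600 lives and
averts about 137,200 major cardiovascular events; about 2.72 million
additional members screened for colorectal cancer save about 33,400 lives
per decade. Per-segment rows (including the separately reported California
Marketplace, e.g. 256 colorectal-screening lives per decade) are in
`res$results`, and `res$summary$percent_annual_death_reduction` gives the
shares of annual condition deaths (1.6% for hypertension at the 66th
percentile).

`table1_summary(load_benchmark_tables(qi_example("benchmarks_2019.csv")))`
summarizes the benchmark distributions: scores range from 47 to 83 across
all segments and percentiles, with Marketplace plans showing the widest
25th–90th spread and Medicare the narrowest.

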