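Package: qualityimpact
Title: Lives Saved and Harms Avoided from Health Plan Quality Improvement
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quality-impact model estimating the population health benefits of
    health plans improving performance on clinical quality measures
    (colorectal cancer screening, controlling high blood pressure) to
    percentile benchmarks. Discretizes plan performance distributions into
    conservative percentile bins, computes measure-eligible denominators from
    enrollment and age-specific disease prevalence, converts numerator gains
    into lives saved and major cardiovascular events averted per decade via
    number-needed-to-treat (NNT) benefit models with lifetime or trial-period
    annualization, aggregates national totals, and supports next-decile and
    market-share sensitivity analyses on plan-level rosters, including a
    seeded synthetic roster generator for fully reproducible testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    rlang,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
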