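# Published reference quantities for the national quality-impact scenario.
# The enrollment/prevalence construction behind the published 66th-percentile
# numerator gains is not publicly available, so those gains function as
# calibration inputs: the shipped synthetic population fixture is back-solved
# to reproduce them through the pipeline, and validation compares the
# benefit-conversion chain against the published downstream figures.

#' Published reference inputs and headline figures
#'
#' Returns the published quantities the model is validated against:
#'
#' * `gains_p66`: members moving into each measure numerator when every plan
#'   below the 66th percentile reaches it, by segment (model inputs).
#' * `lives_p66`, `lives_p90`: published decade lives saved by segment and
#'   nationally (validation references).
#' * `events_p66`, `events_p90`: published national MACE averted (bp only).
#' * `annual_condition_deaths`: annual US deaths from colorectal cancer
#'   (51,869) and hypertension (691,095).
#' * `horizon_years`: 10 (benefits quoted per decade).
#'
#' @return a named list; see details above.
#' @export
reference_inputs <- function() {
  gains_p66 <- tibble::tribble(
    ~measure,        ~segment,         ~numerator_gain,
    "crc_screening", "CA-Marketplace",    20865,
    "crc_screening", "Medicare",        1228663,
    "crc_screening", "Marketplace",      217638,
    "crc_screening", "Commercial",      1274794,
    "bp_control",    "CA-Marketplace",    13880,
    "bp_control",    "Medicare",        1168105,
    "bp_control",    "Medicaid",         875763,
    "bp_control",    "Marketplace",      192372,
    "bp_control",    "Commercial",      2192477
  )
  lives_p66 <- tibble::tribble(
    ~measure,        ~segment,         ~lives_saved,
    "crc_screening", "CA-Marketplace",   257,
    "crc_screening", "Medicare",       15127,
    "crc_screening", "Marketplace",     2680,
    "crc_screening", "Commercial",     15695,
    "crc_screening", "National",       33502,
    "bp_control",    "CA-Marketplace",   330,
    "bp_control",    "National",      110067
  )
  lives_p90 <- tibble::tribble(
    ~measure,        ~segment,         ~lives_saved,
    "crc_screening", "CA-Marketplace",   679,
    "crc_screening", "Medicare",       46027,
    "crc_screening", "Marketplace",     5992,
    "crc_screening", "Commercial",     33412,
    "crc_screening", "National",       85432,
    "bp_control",    "CA-Marketplace",  1320,
    "bp_control",    "Medicare",       80080,
    "bp_control",    "Medicaid",       51760,
    "bp_control",    "Marketplace",    12260,
    "bp_control",    "Commercial",    140060,
    "bp_control",    "National",      280487
  )
  list(
    gains_p66 = gains_p66,
    lives_p66 = lives_p66,
    lives_p90 = lives_p90,
    events_p66 = 137164,
    events_p90 = 335006,
    annual_condition_deaths = c(crc_screening = 51869, bp_control = 691095),
    horizon_years = 10
  )
}

#' Path to a shipped example data file
#'
#' @param file file name under the package's `extdata/`; with no argument,
#'   lists the available files.
#' @return absolute path (or character vector of file names).
#' @export
qi_example <- function(file = NULL) {
  if (is.null(file)) {
    return(dir(system.file("extdata", package = "qualityimpact")))
  }
  path <- system.file("extdata", file, package = "qualityimpact")
  if (path == "") {
    qi_stop(sprintf("no example file '%s' in qualityimpact", file),
            "qi_validation_error")
  }
  path
}
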