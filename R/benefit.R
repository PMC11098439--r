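# Benefit models: number-needed-to-treat constants and the annualization
# scheme that converts a count of newly-benefiting members into lives saved
# (and, where modelled, major cardiovascular events averted) per horizon.

#' Construct a benefit model for one measure
#'
#' A benefit model carries the NNT to avert one death plus the annualization
#' scheme. Two schemes exist and must not be conflated:
#'
#' * `"lifetime"` — the source evidence reports a lifetime benefit (e.g. a
#'   microsimulation of screening over remaining life). Lives saved accrue at
#'   rate 1/`lifetime_years` of the lifetime total per year:
#'   `lives = (gain / nnt_death) * horizon / lifetime_years`.
#' * `"trial"` — the source evidence reports an absolute risk reduction over
#'   a trial follow-up period. The per-follow-up benefit repeats over the
#'   horizon: `lives = (gain / nnt_death) * horizon / trial_followup_years`.
#'
#' @param measure_id measure identifier.
#' @param nnt_death persons treated per death averted (>= 1).
#' @param annualization `"lifetime"` or `"trial"`.
#' @param lifetime_years average remaining life expectancy in years
#'   (required for `"lifetime"`).
#' @param trial_followup_years trial follow-up in years (required for
#'   `"trial"`).
#' @param nnt_event optional NNT to avert one major cardiovascular event
#'   (MACE); `NULL` when the endpoint is not modelled for the measure.
#' @return a `benefit_model` object.
#' @export
benefit_model <- function(measure_id, nnt_death,
                          annualization = c("lifetime", "trial"),
                          lifetime_years = NULL,
                          trial_followup_years = NULL,
                          nnt_event = NULL) {
  annualization <- match.arg(annualization)
  if (!is_scalar_number(nnt_death) || nnt_death < 1) {
    qi_stop("`nnt_death` must be a single number >= 1", "qi_validation_error")
  }
  if (annualization == "lifetime") {
    stopifnot_scalar_positive(lifetime_years, "lifetime_years")
    if (!is.null(trial_followup_years)) {
      qi_stop("lifetime annualization must not set `trial_followup_years`",
              "qi_validation_error")
    }
  } else {
    stopifnot_scalar_positive(trial_followup_years, "trial_followup_years")
    if (!is.null(lifetime_years)) {
      qi_stop("trial annualization must not set `lifetime_years`",
              "qi_validation_error")
    }
  }
  if (!is.null(nnt_event)) stopifnot_scalar_positive(nnt_event, "nnt_event")
  structure(
    list(measure_id = measure_id, nnt_death = nnt_death,
         annualization = annualization, lifetime_years = lifetime_years,
         trial_followup_years = trial_followup_years, nnt_event = nnt_event),
    class = "benefit_model"
  )
}

#' Default benefit models
#'
#' Shipped constants, drawn from the clinical literature underpinning each
#' measure:
#'
#' * Colorectal cancer screening: guideline colonoscopy screening of 50- to
#'   75-year-olds averts 27 deaths per 1000 screened over their lifetimes
#'   (microsimulation evidence behind the USPSTF recommendation), i.e.
#'   NNT 37; annualized over 22 years of average remaining life expectancy
#'   after screening starts at age 50. No MACE endpoint.
#' * Blood pressure control: NNT 101 to prevent one death, derived from the
#'   absolute risk reduction for all-cause mortality in the primary-prevention
#'   arm of a meta-analysis of antihypertensive trials with 4-year median
#'   follow-up. The MACE NNT (80.72) is a calibrated constant back-solved
#'   from the model's published national p66 event total; no directly printed
#'   trial value exists for the measure's composite endpoint.
#'
#' @return named list of [benefit_model()] objects keyed by measure id.
#' @export
default_benefit_models <- function() {
  list(
    crc_screening = benefit_model(
      "crc_screening",
      nnt_death = nnt_from_deaths_per_1000(27),
      annualization = "lifetime",
      lifetime_years = 22
    ),
    bp_control = benefit_model(
      "bp_control",
      nnt_death = 101,
      annualization = "trial",
      trial_followup_years = 4,
      nnt_event = 80.72   # calibrated, see above
    )
  )
}

#' NNT from deaths averted per 1000 treated
#'
#' The number needed to treat is the reciprocal of the absolute risk
#' reduction; with the ARR expressed as deaths averted per 1000 individuals,
#' `NNT = 1000 / deaths_per_1000`. The exact real value is returned;
#' conventional integer reporting rounds half-up.
#'
#' @param deaths_averted_per_1000 deaths averted per 1000 treated, in
#'   (0, 1000\].
#' @param report_integer if `TRUE` (default), return the half-up-rounded
#'   integer NNT; if `FALSE`, the exact real value.
#' @return NNT (persons per death averted).
#' @examples
#' nnt_from_deaths_per_1000(27) # 37
#' @export
nnt_from_deaths_per_1000 <- function(deaths_averted_per_1000,
                                     report_integer = TRUE) {
  if (!is_scalar_number(deaths_averted_per_1000) ||
      deaths_averted_per_1000 <= 0 || deaths_averted_per_1000 > 1000) {
    qi_stop("`deaths_averted_per_1000` must lie in (0, 1000]",
            "qi_validation_error")
  }
  nnt <- 1000 / deaths_averted_per_1000
  if (report_integer) round_half_up(nnt) else nnt
}

#' Lives saved over a horizon from a numerator gain
#'
#' Applies the benefit model's NNT and annualization to the count of members
#' newly meeting the measure numerator, assuming the improvement is sustained
#' over the horizon.
#'
#' @param gain persons newly in the numerator (>= 0).
#' @param model a [benefit_model()].
#' @param horizon_years horizon over which improvement is sustained
#'   (default 10, i.e. per decade).
#' @return expected lives saved over the horizon (real-valued; round only
#'   for reporting).
#' @export
lives_saved <- function(gain, model, horizon_years = 10) {
  stopifnot(inherits(model, "benefit_model"))
  if (any(gain < 0)) qi_stop("`gain` must be non-negative", "qi_validation_error")
  stopifnot_scalar_positive(horizon_years, "horizon_years")
  period <- switch(model$annualization,
    lifetime = model$lifetime_years,
    trial = model$trial_followup_years
  )
  (gain / model$nnt_death) * horizon_years / period
}

#' Major cardiovascular events averted over a horizon
#'
#' Same accrual as [lives_saved()] but against the model's event NNT, always
#' over the trial follow-up period. Returns `NA` when the measure has no
#' modelled event endpoint.
#'
#' @inheritParams lives_saved
#' @return events averted over the horizon, or `NA_real_`.
#' @export
events_averted <- function(gain, model, horizon_years = 10) {
  stopifnot(inherits(model, "benefit_model"))
  if (is.null(model$nnt_event)) return(NA_real_)
  if (any(gain < 0)) qi_stop("`gain` must be non-negative", "qi_validation_error")
  stopifnot_scalar_positive(horizon_years, "horizon_years")
  (gain / model$nnt_event) * horizon_years / model$trial_followup_years
}
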