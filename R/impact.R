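# Impact engine: benchmark-improvement scenarios -> numerator gains ->
# lives saved / events averted, national aggregation, and summary statistics.

#' Numerator gain from binned improvement to a target score
#'
#' Number of members who newly meet the measure numerator when every bin
#' below the target improves to it:
#' `sum_over_bins( weight * denominator * gap(bin, target) / 100 )`.
#'
#' @param bins bin tibble from [make_bins()].
#' @param target_score target benchmark score, percent.
#' @param denominator measure-eligible persons in the segment (>= 0).
#' @return persons newly in the numerator (real-valued).
#' @export
numerator_gain <- function(bins, target_score, denominator) {
  stopifnot(is.data.frame(bins),
            all(c("assumed_score", "population_weight") %in% names(bins)))
  if (!is_scalar_number(denominator) || denominator < 0) {
    qi_stop("`denominator` must be a single non-negative number",
            "qi_validation_error")
  }
  gaps <- improvement_gap(bins$assumed_score, target_score)
  sum(bins$population_weight * denominator * gaps / 100)
}

#' Assemble one impact result row
#'
#' @param measure_id,segment,scenario identifiers for the row.
#' @param numerator_gain persons newly in the numerator.
#' @param model a [benefit_model()].
#' @param horizon_years scenario horizon (default 10 years).
#' @param denominator,target_score optional provenance columns.
#' @return one-row tibble with columns `measure`, `segment`, `scenario`,
#'   `denominator`, `target_score`, `numerator_gain`, `lives_saved`,
#'   `events_averted`, `annual_lives_saved`.
#' @export
impact_result <- function(measure_id, segment, scenario, numerator_gain,
                          model, horizon_years = 10,
                          denominator = NA_real_, target_score = NA_real_) {
  lives <- lives_saved(numerator_gain, model, horizon_years)
  events <- events_averted(numerator_gain, model, horizon_years)
  tibble::tibble(
    measure = measure_id,
    segment = segment,
    scenario = scenario,
    denominator = denominator,
    target_score = target_score,
    numerator_gain = numerator_gain,
    lives_saved = lives,
    events_averted = events,
    annual_lives_saved = lives / horizon_years
  )
}

#' Aggregate segment impact results into a national total
#'
#' Component-wise sum over the included segments. The California Marketplace
#' is a spotlight segment reported on its own and is never folded into
#' national totals.
#'
#' @param results tibble of impact rows (one measure, one scenario).
#' @param segments segments to include; default: every segment present
#'   except `"CA-Marketplace"`.
#' @return one-row tibble with `segment = "National"`.
#' @export
aggregate_national <- function(results, segments = NULL) {
  stopifnot(is.data.frame(results), nrow(results) >= 1L)
  if (length(unique(results$measure)) != 1L ||
      length(unique(results$scenario)) != 1L) {
    qi_stop("cannot aggregate across mixed measures or scenarios",
            "qi_validation_error")
  }
  if (is.null(segments)) {
    segments <- setdiff(unique(results$segment), "CA-Marketplace")
  } else {
    segments <- setdiff(segments, "CA-Marketplace")
  }
  keep <- results[results$segment %in% segments, , drop = FALSE]
  sum_or_na <- function(x) if (all(is.na(x))) NA_real_ else sum(x, na.rm = TRUE)
  tibble::tibble(
    measure = keep$measure[1],
    segment = "National",
    scenario = keep$scenario[1],
    denominator = sum_or_na(keep$denominator),
    target_score = NA_real_,
    numerator_gain = sum_or_na(keep$numerator_gain),
    lives_saved = sum_or_na(keep$lives_saved),
    events_averted = sum_or_na(keep$events_averted),
    annual_lives_saved = sum_or_na(keep$annual_lives_saved)
  )
}

#' Percent reduction in annual condition-specific deaths
#'
#' Expresses decade lives saved as a share of the condition's annual death
#' toll: `100 * (lives_per_horizon / horizon_years) / annual_deaths`.
#' Conventionally reported to one decimal (round half-up at the reporting
#' layer); the exact value is returned.
#'
#' @param lives_per_horizon lives saved over the horizon.
#' @param horizon_years horizon length in years.
#' @param annual_condition_deaths annual deaths from the condition (> 0).
#' @return percent reduction (exact real value).
#' @export
percent_annual_death_reduction <- function(lives_per_horizon, horizon_years,
                                           annual_condition_deaths) {
  stopifnot_scalar_positive(horizon_years, "horizon_years")
  if (!is_scalar_number(annual_condition_deaths) ||
      annual_condition_deaths <= 0) {
    qi_stop("`annual_condition_deaths` must be positive",
            "qi_validation_error")
  }
  100 * (lives_per_horizon / horizon_years) / annual_condition_deaths
}

#' Reconcile a computed quantity against an externally reported value
#'
#' Several published headline figures embed unstated intermediate rounding or
#' internal inconsistencies and are not exactly reproducible from the stated
#' model (e.g. a printed national total differing from the sum of its printed
#' segment values). This helper makes such residuals loud and auditable: it
#' compares a computed value to the reported one and emits a structured
#' warning (class `qi_reported_mismatch`) when the relative discrepancy
#' exceeds `tol_rel`, instead of silently tuning either number.
#'
#' @param computed value produced by this package.
#' @param reported externally published value.
#' @param label short description used in the warning message.
#' @param tol_rel relative tolerance before warning (default 0.01).
#' @return invisibly, a list with `computed`, `reported`, `rel_diff`,
#'   `consistent`.
#' @export
reconcile_reported <- function(computed, reported, label, tol_rel = 0.01) {
  rel <- abs(computed - reported) / abs(reported)
  ok <- rel <= tol_rel
  if (!ok) {
    qi_warn(sprintf(
      "%s: computed %.6g differs from reported %.6g by %.2f%% (> %.2f%% tolerance); reported value not reproduced",
      label, computed, reported, 100 * rel, 100 * tol_rel),
      "qi_reported_mismatch")
  }
  invisible(list(computed = computed, reported = reported,
                 rel_diff = rel, consistent = ok))
}
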