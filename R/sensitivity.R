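# Sensitivity analyses: next-decile improvement targets and plan-level
# (actual market share) numerator gains on a plan roster.

#' Plan roster constructor / validator
#'
#' @param plans data frame with columns `plan_id`, `segment`, `enrollment`
#'   (> 0), `score` (percent in \[0, 100\]).
#' @return tibble of validated plan records.
#' @export
plan_roster <- function(plans) {
  plans <- tibble::as_tibble(plans)
  stopifnot(all(c("plan_id", "segment", "enrollment", "score") %in% names(plans)))
  if (nrow(plans) == 0L) {
    qi_stop("plan roster is empty", "qi_validation_error")
  }
  if (any(plans$enrollment <= 0)) {
    qi_stop("plan enrollment must be positive", "qi_validation_error")
  }
  if (any(plans$score < 0 | plans$score > 100)) {
    qi_stop("plan scores must lie in [0, 100]", "qi_validation_error")
  }
  plans
}

#' Load a plan roster from CSV
#'
#' Schema: `plan_id,segment,enrollment,score`.
#' @param path roster CSV path.
#' @return validated roster tibble.
#' @export
load_plan_roster <- function(path) {
  plan_roster(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Assign performance deciles to plans
#'
#' Decile 1 holds the lowest scores. With `basis = "plans"` deciles are
#' deciles of plans (enrollment-unweighted score ranks); with
#' `basis = "members"` they are deciles of members (cumulative enrollment
#' share at the plan's score rank).
#'
#' @param plans a [plan_roster()].
#' @param basis `"plans"` or `"members"`.
#' @return integer vector of deciles in 1..10, aligned with `plans` rows.
#' @export
assign_deciles <- function(plans, basis = c("plans", "members")) {
  basis <- match.arg(basis)
  plans <- plan_roster(plans)
  ord <- order(plans$score, seq_len(nrow(plans)))
  frac <- switch(basis,
    plans = seq_len(nrow(plans)) / nrow(plans),
    members = cumsum(plans$enrollment[ord]) / sum(plans$enrollment)
  )
  dec <- pmin(10L, as.integer(ceiling(frac * 10 - 1e-12)))
  dec[dec < 1L] <- 1L
  out <- integer(nrow(plans))
  out[ord] <- dec
  out
}

# upper score boundary of decile d: the score at cumulative fraction d/10
# (order statistic / weighted analogue)
decile_boundary <- function(plans, d, basis) {
  ord <- order(plans$score, seq_len(nrow(plans)))
  s <- plans$score[ord]
  p <- min(1, d / 10)
  if (basis == "plans") {
    s[max(1L, ceiling(p * length(s) - 1e-12))]
  } else {
    cw <- cumsum(plans$enrollment[ord]) / sum(plans$enrollment)
    s[which(cw >= p - 1e-12)[1]]
  }
}

#' Next-decile improvement targets
#'
#' The incremental-improvement scenario: each plan below the 66th-percentile
#' benchmark improves only to the upper score boundary of the next
#' performance decile, capped at the benchmark; plans at or above the
#' benchmark keep their own score. Targets never fall below a plan's score.
#'
#' @param plans a [plan_roster()].
#' @param benchmark_p66 the 66th-percentile benchmark score, percent.
#' @param decile_basis `"plans"` (deciles of the roster's plans; default) or
#'   `"members"` (enrollment-weighted deciles).
#' @return named numeric vector of target scores, names = `plan_id`.
#' @export
next_decile_targets <- function(plans, benchmark_p66,
                                decile_basis = c("plans", "members")) {
  decile_basis <- match.arg(decile_basis)
  plans <- plan_roster(plans)
  dec <- assign_deciles(plans, decile_basis)
  targets <- vapply(seq_len(nrow(plans)), function(i) {
    s <- plans$score[i]
    if (s >= benchmark_p66) return(s)
    nxt <- decile_boundary(plans, dec[i] + 1L, decile_basis)
    min(benchmark_p66, max(s, nxt))
  }, numeric(1))
  stats::setNames(targets, plans$plan_id)
}

#' Plan-level numerator gain under actual or even market share
#'
#' Exact plan-by-plan counterpart of the binned engine:
#' `sum_i denom_i * (target_i - score_i) / 100`, where each plan's slice of
#' the segment denominator is either an even split (`"even"`, the
#' no-enrollment-data assumption) or proportional to enrollment
#' (`"by_enrollment"`, the actual-market-share sensitivity).
#'
#' @param plans a [plan_roster()].
#' @param targets named numeric vector of target scores (names = plan ids),
#'   e.g. from [next_decile_targets()], or a single score applied to all
#'   plans below it.
#' @param denominator the segment's measure-eligible denominator, persons.
#' @param share_rule `"even"` or `"by_enrollment"`.
#' @return persons newly in the numerator.
#' @export
plan_level_numerator_gain <- function(plans, targets, denominator,
                                      share_rule = c("even", "by_enrollment")) {
  share_rule <- match.arg(share_rule)
  plans <- plan_roster(plans)
  if (length(targets) == 1L && is.null(names(targets))) {
    targets <- stats::setNames(pmax(plans$score, targets), plans$plan_id)
  }
  targets <- targets[as.character(plans$plan_id)]
  if (anyNA(targets)) {
    qi_stop("every plan needs a target score", "qi_validation_error")
  }
  if (any(targets < plans$score - 1e-12)) {
    qi_stop("target score below a plan's own score", "qi_validation_error")
  }
  shares <- switch(share_rule,
    even = rep(1 / nrow(plans), nrow(plans)),
    by_enrollment = plans$enrollment / sum(plans$enrollment)
  )
  sum(shares * denominator * (targets - plans$score) / 100)
}

#' Relative change between a baseline and a variant estimate
#'
#' @param baseline baseline lives saved (> 0).
#' @param variant variant lives saved.
#' @return signed percent change, `100 * (variant - baseline) / baseline`.
#' @export
relative_change <- function(baseline, variant) {
  if (!is_scalar_number(baseline) || baseline <= 0) {
    qi_stop("`baseline` must be positive", "qi_validation_error")
  }
  100 * (variant - baseline) / baseline
}

#' Sensitivity report comparing a variant scenario to baseline
#'
#' @param baseline_lives,variant_lives lives saved under each assumption.
#' @param label description of the variant.
#' @return one-row tibble with `label`, `baseline_lives`, `variant_lives`,
#'   `relative_change` (signed percent).
#' @export
sensitivity_report <- function(baseline_lives, variant_lives, label = "") {
  tibble::tibble(
    label = label,
    baseline_lives = baseline_lives,
    variant_lives = variant_lives,
    relative_change = relative_change(baseline_lives, variant_lives)
  )
}
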