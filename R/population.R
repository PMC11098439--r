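# Measure-eligible denominator populations: enrollment by age band, optional
# age-specific disease prevalence, and proration over partially overlapping
# bands. Age bands are closed integer intervals in years; a band [lo, hi]
# spans hi - lo + 1 single years of age, assumed uniformly populated within
# the band (no finer distribution is available).

#' Segment enrollment by age band
#'
#' @param segment segment identifier.
#' @param bands data frame with columns `age_lo`, `age_hi`, `enrollment`
#'   (member counts, non-negative). Bands must be non-overlapping.
#' @return a `segment_population` object; `total_enrollment` is the band sum.
#' @export
segment_population <- function(segment, bands) {
  bands <- as.data.frame(bands)
  needed <- c("age_lo", "age_hi", "enrollment")
  stopifnot(all(needed %in% names(bands)))
  if (any(bands$age_lo > bands$age_hi)) {
    qi_stop("age bands must have age_lo <= age_hi", "qi_validation_error")
  }
  if (any(bands$enrollment < 0)) {
    qi_stop("enrollment counts must be non-negative", "qi_validation_error")
  }
  ord <- order(bands$age_lo)
  bands <- bands[ord, needed, drop = FALSE]
  if (nrow(bands) > 1L &&
      any(bands$age_lo[-1] <= bands$age_hi[-nrow(bands)])) {
    qi_stop(sprintf("age bands overlap for segment %s", segment),
            "qi_validation_error")
  }
  structure(
    list(segment = segment, bands = tibble::as_tibble(bands),
         total_enrollment = sum(bands$enrollment)),
    class = "segment_population"
  )
}

#' Age-specific prevalence table for a condition
#'
#' @param condition condition identifier (e.g. `"hypertension"`).
#' @param bands data frame with columns `age_lo`, `age_hi`, `rate`
#'   (prevalence fractions in \[0, 1\]).
#' @return a `prevalence_table` object.
#' @export
prevalence_table <- function(condition, bands) {
  bands <- as.data.frame(bands)
  stopifnot(all(c("age_lo", "age_hi", "rate") %in% names(bands)))
  if (any(bands$rate < 0) || any(bands$rate > 1)) {
    qi_stop("prevalence rates must lie in [0, 1]", "qi_validation_error")
  }
  structure(
    list(condition = condition,
         bands = tibble::as_tibble(bands[order(bands$age_lo),
                                         c("age_lo", "age_hi", "rate")])),
    class = "prevalence_table"
  )
}

#' Load segment populations from CSV
#'
#' Schema: `segment,age_lo,age_hi,enrollment`.
#'
#' @param path population CSV path.
#' @return named list of [segment_population()] objects, one per segment.
#' @export
load_population <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  split_df <- split(df, df$segment)
  out <- lapply(names(split_df), function(seg) {
    segment_population(seg, split_df[[seg]])
  })
  names(out) <- names(split_df)
  out
}

#' Load a prevalence table from CSV
#'
#' Schema: `condition,age_lo,age_hi,rate`.
#'
#' @param path prevalence CSV path.
#' @param condition which condition's rows to keep.
#' @return a [prevalence_table()].
#' @export
load_prevalence <- function(path, condition = "hypertension") {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df <- df[df$condition == condition, , drop = FALSE]
  if (nrow(df) == 0L) {
    qi_stop(sprintf("no prevalence rows for condition %s in %s",
                    condition, path),
            "qi_data_unavailable")
  }
  prevalence_table(condition, df)
}

# years of overlap between two closed integer age intervals
overlap_years <- function(lo1, hi1, lo2, hi2) {
  pmax(0, pmin(hi1, hi2) - pmax(lo1, lo2) + 1)
}

# overlap-weighted mean prevalence over an enrollment band, assuming uniform
# age distribution within bands; ages uncovered by the prevalence table get
# rate 0 with a warning
band_rate <- function(lo, hi, prevalence) {
  pb <- prevalence$bands
  ov <- overlap_years(lo, hi, pb$age_lo, pb$age_hi)
  width <- hi - lo + 1
  if (sum(ov) < width) {
    qi_warn(sprintf(
      "prevalence table (%s) does not cover all of ages %d-%d; uncovered years treated as rate 0",
      prevalence$condition, lo, hi), "qi_partial_coverage")
  }
  sum(ov * pb$rate) / width
}

#' Measure-eligible denominator for a segment
#'
#' Computes the number of members in a segment eligible for a measure:
#' * screening-type measures (`uses_prevalence = FALSE`): enrollment within
#'   the measure's eligible age window;
#' * prevalence-conditioned measures (`uses_prevalence = TRUE`): enrollment
#'   in the window times age-specific condition prevalence.
#'
#' Enrollment bands only partially inside the eligible window are prorated
#' uniformly by years of overlap, with a warning (no within-band age
#' distribution is available).
#'
#' @param pop a [segment_population()].
#' @param measure a [measure_spec()].
#' @param prevalence a [prevalence_table()]; required when the measure uses
#'   prevalence, ignored otherwise.
#' @return non-negative real person count (not rounded).
#' @export
eligible_denominator <- function(pop, measure, prevalence = NULL) {
  stopifnot(inherits(pop, "segment_population"),
            inherits(measure, "measure_spec"))
  if (measure$uses_prevalence && is.null(prevalence)) {
    qi_stop(sprintf("measure %s requires a prevalence table",
                    measure$measure_id),
            "qi_validation_error")
  }
  lo <- measure$eligible_ages[1]
  hi <- measure$eligible_ages[2]
  b <- pop$bands
  ov <- overlap_years(b$age_lo, b$age_hi, lo, hi)
  width <- b$age_hi - b$age_lo + 1
  frac <- ov / width
  partial <- which(frac > 0 & frac < 1)
  if (length(partial)) {
    qi_warn(sprintf(
      "segment %s: band(s) %s only partially overlap eligible ages %d-%d; prorated uniformly",
      pop$segment,
      paste(sprintf("%d-%d", b$age_lo[partial], b$age_hi[partial]),
            collapse = ", "),
      lo, hi), "qi_prorated_band")
  }
  eligible <- b$enrollment * frac
  if (!measure$uses_prevalence) {
    return(sum(eligible))
  }
  # rate over the eligible part of each band
  rates <- mapply(function(blo, bhi, f) {
    if (f <= 0) return(0)
    band_rate(max(blo, lo), min(bhi, hi), prevalence)
  }, b$age_lo, b$age_hi, frac)
  sum(eligible * rates)
}
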