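# Measure definitions, percentile benchmark tables, and the conservative
# discretization of a segment's plan-performance distribution into bins.

#' Reported benchmark percentiles
#'
#' Health-plan performance distributions are summarized at five reported
#' percentiles (25th, 50th, 66th, 75th, 90th); all binning logic keys off
#' this set.
#' @export
benchmark_percentiles <- c(25, 50, 66, 75, 90)

# Fixed bin edge set: the reported percentiles plus the distribution
# endpoints. The (90,100] bin always carries the 90th-percentile score, so it
# contributes zero gain for any target at or below the 90th percentile.
bin_edges <- c(0, 25, 50, 66, 75, 90, 100)

#' Recognized market segments
#' @export
market_segments <- c("Medicare", "Medicaid", "Marketplace", "Commercial",
                     "CA-Marketplace")

#' Measure specification
#'
#' Returns the definition of one of the two modelled quality measures:
#'
#' * `crc_screening` — colorectal cancer screening (CBE #0034): members aged
#'   50-75 screened per guidelines. The whole age-eligible enrollment is the
#'   denominator; no prevalence weighting.
#' * `bp_control` — controlling high blood pressure (CBE #0018): hypertensive
#'   members with SBP < 140 mm Hg and DBP < 90 mm Hg. The denominator is
#'   enrollment times age-specific hypertension prevalence over ages 18-85
#'   (configurable window; the conventional HEDIS adult denominator).
#'
#' @param measure_id one of `"crc_screening"`, `"bp_control"`.
#' @param eligible_ages optional length-2 integer vector overriding the
#'   default eligible age window.
#' @return a `measure_spec` list with fields `measure_id`, `name`,
#'   `numerator_definition`, `eligible_ages`, `uses_prevalence`.
#' @export
measure_spec <- function(measure_id = c("crc_screening", "bp_control"),
                         eligible_ages = NULL) {
  measure_id <- match.arg(measure_id)
  spec <- switch(measure_id,
    crc_screening = list(
      measure_id = "crc_screening",
      name = "Colorectal cancer screening",
      numerator_definition = "members screened for colorectal cancer per guidelines",
      eligible_ages = c(50L, 75L),
      uses_prevalence = FALSE
    ),
    bp_control = list(
      measure_id = "bp_control",
      name = "Controlling high blood pressure",
      numerator_definition = "hypertensive members with SBP <140 mm Hg and DBP <90 mm Hg",
      eligible_ages = c(18L, 85L),
      uses_prevalence = TRUE
    )
  )
  if (!is.null(eligible_ages)) {
    stopifnot(length(eligible_ages) == 2L)
    if (eligible_ages[1] >= eligible_ages[2]) {
      qi_stop("eligible age range must have lower bound < upper bound",
              "qi_validation_error")
    }
    spec$eligible_ages <- as.integer(eligible_ages)
  }
  structure(spec, class = "measure_spec")
}

#' Construct a percentile benchmark table
#'
#' One measure x market-segment row of a benchmark distribution: the measure
#' score (percent of the denominator meeting the numerator) at the 25th,
#' 50th, 66th, 75th and 90th percentiles of the plan distribution.
#'
#' @param measure_id measure identifier.
#' @param segment market segment name.
#' @param scores numeric length-5 vector of scores in \[0, 100\], ordered by
#'   percentile (25, 50, 66, 75, 90). Must be non-decreasing.
#' @return a `benchmark_table` object.
#' @export
benchmark_table <- function(measure_id, segment, scores) {
  scores <- as.numeric(scores)
  if (length(scores) != 5L || anyNA(scores)) {
    qi_stop(sprintf("benchmark scores for (%s, %s) must be 5 non-missing values",
                    measure_id, segment),
            "qi_validation_error")
  }
  if (any(scores < 0) || any(scores > 100)) {
    qi_stop("benchmark scores must lie in [0, 100]", "qi_validation_error")
  }
  if (is.unsorted(scores)) {
    qi_stop(sprintf(
      "benchmark scores for (%s, %s) are not non-decreasing across percentiles",
      measure_id, segment), "qi_validation_error")
  }
  names(scores) <- as.character(benchmark_percentiles)
  structure(list(measure_id = measure_id, segment = segment, scores = scores),
            class = "benchmark_table")
}

#' @export
print.benchmark_table <- function(x, ...) {
  cat(sprintf("<benchmark_table> %s / %s\n", x$measure_id, x$segment))
  print(x$scores)
  invisible(x)
}

#' Load one benchmark table from CSV
#'
#' The CSV schema is `measure_id,segment,p25,p50,p66,p75,p90`; empty score
#' cells mark a measure/segment pair for which no distribution data exist
#' (for example, Medicaid has no colorectal-screening distribution). Such
#' pairs raise a condition of class `qi_data_unavailable` rather than being
#' silently treated as zero.
#'
#' @param path path to the benchmark CSV.
#' @param measure_id,segment the row to extract.
#' @return a validated [benchmark_table()].
#' @export
load_benchmark_table <- function(path, measure_id, segment) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("measure_id", "segment", "p25", "p50", "p66", "p75", "p90")
  if (!all(needed %in% names(df))) {
    qi_stop(sprintf("benchmark CSV %s lacks columns: %s", path,
                    paste(setdiff(needed, names(df)), collapse = ", ")),
            "qi_validation_error")
  }
  row <- df[df$measure_id == measure_id & df$segment == segment, , drop = FALSE]
  if (nrow(row) == 0L) {
    qi_stop(sprintf("no benchmark row for (%s, %s) in %s",
                    measure_id, segment, path),
            "qi_data_unavailable")
  }
  scores <- suppressWarnings(as.numeric(row[1, c("p25", "p50", "p66", "p75", "p90")]))
  if (anyNA(scores)) {
    qi_stop(sprintf("benchmark data unavailable for (%s, %s)",
                    measure_id, segment),
            "qi_data_unavailable")
  }
  benchmark_table(measure_id, segment, scores)
}

#' Load all available benchmark tables from CSV
#'
#' @param path path to the benchmark CSV (same schema as
#'   [load_benchmark_table()]).
#' @return named list of `benchmark_table` objects, names
#'   `"<measure_id>.<segment>"`; rows with missing scores are skipped.
#' @export
load_benchmark_tables <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  out <- list()
  for (i in seq_len(nrow(df))) {
    tab <- tryCatch(
      load_benchmark_table(path, df$measure_id[i], df$segment[i]),
      qi_data_unavailable = function(e) NULL
    )
    if (!is.null(tab)) {
      out[[paste(tab$measure_id, tab$segment, sep = ".")]] <- tab
    }
  }
  out
}

#' Discretize a benchmark table into percentile bins
#'
#' Partitions the plan distribution (0, 100\] into six bins with edges at the
#' reported percentiles \{0, 25, 50, 66, 75, 90, 100\}. Each bin's assumed
#' score follows the conservative next-highest-percentile rule: every plan
#' between two reported percentiles is assumed to already perform at the
#' upper one, so modelled improvement gaps understate true gaps. The top bin
#' (90, 100\] keeps the 90th-percentile score.
#'
#' Population weights follow `weight_rule`:
#' * `"percentile_width"` (default): weight = (upper - lower) / 100, i.e.
#'   plan market share uniform over percentile rank.
#' * `"equal_bins"`: each of the six bins carries weight 1/6.
#'
#' @param table a [benchmark_table()].
#' @param weight_rule `"percentile_width"` or `"equal_bins"`.
#' @return tibble with columns `lower_percentile`, `upper_percentile`,
#'   `assumed_score`, `population_weight`; weights sum to 1.
#' @export
make_bins <- function(table, weight_rule = c("percentile_width", "equal_bins")) {
  stopifnot(inherits(table, "benchmark_table"))
  weight_rule <- match.arg(weight_rule)
  lower <- bin_edges[-length(bin_edges)]
  upper <- bin_edges[-1]
  # assumed score at the bin's upper reported percentile; top bin reuses p90
  assumed <- unname(table$scores[c("25", "50", "66", "75", "90", "90")])
  weight <- switch(weight_rule,
    percentile_width = (upper - lower) / 100,
    equal_bins = rep(1 / 6, 6L)
  )
  tibble::tibble(
    lower_percentile = lower,
    upper_percentile = upper,
    assumed_score = assumed,
    population_weight = weight
  )
}

#' Improvement gap to a target score
#'
#' Percentage-point shortfall of an assumed bin score below a target
#' benchmark score; plans at or above the target contribute nothing
#' (improvement is never negative).
#'
#' @param assumed_score numeric vector of bin (or plan) scores, percent.
#' @param target_score scalar target score in \[0, 100\].
#' @return `pmax(0, target_score - assumed_score)`, percentage points.
#' @export
improvement_gap <- function(assumed_score, target_score) {
  if (!is_scalar_number(target_score) || target_score < 0 || target_score > 100) {
    qi_stop("`target_score` must be a single value in [0, 100]",
            "qi_validation_error")
  }
  pmax(0, target_score - assumed_score)
}

#' Conservative bin-assumed score for plan-level scores
#'
#' Maps each true plan score to the score it is assumed to hold under the
#' conservative binning rule: the smallest reported-percentile score at or
#' above it (scores above the 90th-percentile score keep the 90th-percentile
#' score, which still yields a zero gap for any target at or below it).
#' Guarantees assumed score >= true score for plans below the 90th-percentile
#' score, hence assumed gap <= true gap.
#'
#' @param scores numeric vector of true plan scores, percent.
#' @param table a [benchmark_table()].
#' @return numeric vector of assumed scores.
#' @export
assume_bin_score <- function(scores, table) {
  stopifnot(inherits(table, "benchmark_table"))
  pct_scores <- unname(table$scores)
  vapply(scores, function(s) {
    at_or_above <- pct_scores[pct_scores >= s]
    if (length(at_or_above)) min(at_or_above) else pct_scores[5L]
  }, numeric(1))
}
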