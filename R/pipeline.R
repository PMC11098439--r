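# Pipeline orchestration and reporting: run every measure x segment x
# scenario, aggregate national totals, run roster sensitivity analyses, and
# write deterministic CSV/JSON/text outputs.

#' Build a pipeline run configuration
#'
#' Defaults point at the shipped fixtures: the 2019-measurement-year
#' benchmark distributions and a synthetic population/prevalence pair
#' calibrated so the 66th-percentile numerator gains reproduce the published
#' reference scenario.
#'
#' @param benchmarks,population,prevalence paths to the benchmark,
#'   population and prevalence CSVs.
#' @param plans optional plan roster CSV path or roster tibble (enables the
#'   `next_decile` scenario and market-share sensitivity).
#' @param measures measure ids to run.
#' @param scenarios subset of `c("p66", "p90", "next_decile")`.
#' @param weight_rule bin weight rule, see [make_bins()].
#' @param horizon_years scenario horizon (default 10).
#' @param benefit_models named list of [benefit_model()]s keyed by measure.
#' @param annual_condition_deaths named vector of annual US condition deaths
#'   keyed by measure (for percent-reduction reporting).
#' @param out_dir optional output directory; when set, [run_pipeline()]
#'   writes `results.csv`, `summary.json`, `report.txt` and `run_log.json`.
#' @param seed integer seed recorded in the run log (the deterministic
#'   pipeline itself draws no random numbers; the seed feeds any synthetic
#'   inputs generated alongside).
#' @return a `run_config` object.
#' @export
run_config <- function(benchmarks = qi_example("benchmarks_2019.csv"),
                       population = qi_example("population_synthetic.csv"),
                       prevalence = qi_example("prevalence_synthetic.csv"),
                       plans = NULL,
                       measures = c("crc_screening", "bp_control"),
                       scenarios = c("p66", "p90"),
                       weight_rule = c("percentile_width", "equal_bins"),
                       horizon_years = 10,
                       benefit_models = default_benefit_models(),
                       annual_condition_deaths =
                         reference_inputs()$annual_condition_deaths,
                       out_dir = NULL,
                       seed = 1L) {
  weight_rule <- match.arg(weight_rule)
  bad <- setdiff(scenarios, c("p66", "p90", "next_decile"))
  if (length(bad)) {
    qi_stop(paste("unknown scenario(s):", paste(bad, collapse = ", ")),
            "qi_validation_error")
  }
  stopifnot_scalar_positive(horizon_years, "horizon_years")
  for (m in measures) {
    if (is.null(benefit_models[[m]])) {
      qi_stop(sprintf("no benefit model for measure %s", m),
              "qi_validation_error")
    }
  }
  structure(
    list(benchmarks = benchmarks, population = population,
         prevalence = prevalence, plans = plans, measures = measures,
         scenarios = scenarios, weight_rule = weight_rule,
         horizon_years = horizon_years, benefit_models = benefit_models,
         annual_condition_deaths = annual_condition_deaths,
         out_dir = out_dir, seed = as.integer(seed)),
    class = "run_config"
  )
}

#' Load a run configuration from YAML
#'
#' Recognized keys mirror the arguments of [run_config()]; benefit-model
#' constants may be overridden under `benefit_models:` as
#' `<measure>: {nnt_death, annualization, lifetime_years,
#' trial_followup_years, nnt_event}`.
#'
#' @param path YAML file path.
#' @return a `run_config` object.
#' @export
load_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  models <- default_benefit_models()
  if (!is.null(y$benefit_models)) {
    for (m in names(y$benefit_models)) {
      spec <- y$benefit_models[[m]]
      models[[m]] <- benefit_model(
        m, nnt_death = spec$nnt_death,
        annualization = spec$annualization,
        lifetime_years = spec$lifetime_years,
        trial_followup_years = spec$trial_followup_years,
        nnt_event = spec$nnt_event)
    }
  }
  deaths <- reference_inputs()$annual_condition_deaths
  if (!is.null(y$annual_condition_deaths)) {
    deaths <- unlist(y$annual_condition_deaths)
  }
  args <- list(
    plans = y$plans,
    measures = y$measures %||% c("crc_screening", "bp_control"),
    scenarios = y$scenarios %||% c("p66", "p90"),
    weight_rule = y$weight_rule %||% "percentile_width",
    horizon_years = y$horizon_years %||% 10,
    benefit_models = models,
    annual_condition_deaths = deaths,
    out_dir = y$out_dir,
    seed = y$seed %||% 1L
  )
  for (k in c("benchmarks", "population", "prevalence")) {
    if (!is.null(y[[k]])) args[[k]] <- y[[k]]
  }
  do.call(run_config, args)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# empty results skeleton so an empty scenario list still yields a valid,
# writable frame
empty_results <- function() {
  tibble::tibble(
    measure = character(), segment = character(), scenario = character(),
    denominator = numeric(), target_score = numeric(),
    numerator_gain = numeric(), lives_saved = numeric(),
    events_averted = numeric(), annual_lives_saved = numeric(),
    note = character()
  )
}

#' Run the full quality-impact pipeline
#'
#' Executes, for every configured measure x segment x scenario: eligible
#' denominator from enrollment (and prevalence where the measure needs it),
#' conservative percentile binning of the benchmark distribution, numerator
#' gain to the scenario target, and NNT benefit conversion; then aggregates
#' national totals (California Marketplace always reported separately) and,
#' when a plan roster is supplied, next-decile / market-share sensitivity.
#' Measure/segment pairs without benchmark data are flagged
#' `"data unavailable"` and excluded from totals, never zero-filled.
#'
#' @param config a [run_config()].
#' @return list with `results` (segment rows), `national` (per measure x
#'   scenario), `sensitivity` (tibble or `NULL`), `summary` (named list used
#'   for the JSON summary), and `files` (paths written, if `out_dir` set).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  pops <- load_population(config$population)
  prev <- tryCatch(load_prevalence(config$prevalence),
                   qi_data_unavailable = function(e) NULL)
  rows <- list()
  for (m in config$measures) {
    spec <- measure_spec(m)
    model <- config$benefit_models[[m]]
    for (seg in names(pops)) {
      denom <- eligible_denominator(
        pops[[seg]], spec,
        prevalence = if (spec$uses_prevalence) prev else NULL)
      tab <- tryCatch(
        load_benchmark_table(config$benchmarks, m, seg),
        qi_data_unavailable = function(e) NULL,
        qi_error = function(e) NULL)
      for (sc in setdiff(config$scenarios, "next_decile")) {
        if (is.null(tab)) {
          rows[[length(rows) + 1L]] <- tibble::tibble(
            measure = m, segment = seg, scenario = sc,
            denominator = denom, target_score = NA_real_,
            numerator_gain = NA_real_, lives_saved = NA_real_,
            events_averted = NA_real_, annual_lives_saved = NA_real_,
            note = "data unavailable")
          next
        }
        target <- unname(tab$scores[[sub("^p", "", sc)]])
        bins <- make_bins(tab, config$weight_rule)
        gain <- numerator_gain(bins, target, denom)
        res <- impact_result(m, seg, sc, gain, model,
                             config$horizon_years,
                             denominator = denom, target_score = target)
        res$note <- ""
        rows[[length(rows) + 1L]] <- res
      }
    }
  }
  results <- if (length(rows)) do.call(rbind, rows) else empty_results()
  # sorted, deterministic row order
  if (nrow(results)) {
    results <- results[order(results$measure, results$scenario,
                             results$segment), , drop = FALSE]
  }

  national <- empty_results()[0, setdiff(names(empty_results()), "note")]
  for (m in unique(results$measure)) {
    for (sc in unique(results$scenario)) {
      block <- results[results$measure == m & results$scenario == sc &
                         results$note == "", , drop = FALSE]
      if (nrow(block)) {
        national <- rbind(national,
                          aggregate_national(block[, names(block) != "note"]))
      }
    }
  }

  sensitivity <- NULL
  if (!is.null(config$plans) && "next_decile" %in% config$scenarios) {
    roster_all <- if (is.character(config$plans)) {
      load_plan_roster(config$plans)
    } else plan_roster(config$plans)
    sens_rows <- list()
    for (m in config$measures) {
      spec <- measure_spec(m)
      model <- config$benefit_models[[m]]
      for (seg in intersect(unique(roster_all$segment), names(pops))) {
        roster <- roster_all[roster_all$segment == seg, , drop = FALSE]
        tab <- tryCatch(load_benchmark_table(config$benchmarks, m, seg),
                        qi_error = function(e) NULL)
        if (is.null(tab)) next
        denom <- eligible_denominator(
          pops[[seg]], spec,
          prevalence = if (spec$uses_prevalence) prev else NULL)
        p66 <- unname(tab$scores[["66"]])
        baseline_gain <- numerator_gain(make_bins(tab, config$weight_rule),
                                        p66, denom)
        baseline <- lives_saved(baseline_gain, model, config$horizon_years)
        targets <- next_decile_targets(roster, p66)
        for (rule in c("even", "by_enrollment")) {
          vgain <- plan_level_numerator_gain(roster, targets, denom, rule)
          variant <- lives_saved(vgain, model, config$horizon_years)
          sens_rows[[length(sens_rows) + 1L]] <- cbind(
            tibble::tibble(measure = m, segment = seg),
            sensitivity_report(baseline, variant,
                               label = paste0("next_decile/", rule)))
        }
      }
    }
    if (length(sens_rows)) sensitivity <- do.call(rbind, sens_rows)
  }

  summary <- list(
    seed = config$seed,
    config_hash = rlang::hash(config[setdiff(names(config), "out_dir")]),
    horizon_years = config$horizon_years,
    national = national,
    percent_annual_death_reduction = {
      pr <- list()
      for (i in seq_len(nrow(national))) {
        m <- national$measure[i]
        deaths <- config$annual_condition_deaths[[m]]
        if (!is.null(deaths) && !is.na(national$lives_saved[i])) {
          pr[[paste(m, national$scenario[i], sep = ".")]] <-
            percent_annual_death_reduction(national$lives_saved[i],
                                           config$horizon_years, deaths)
        }
      }
      pr
    }
  )

  files <- NULL
  if (!is.null(config$out_dir)) {
    files <- write_run_outputs(results, national, sensitivity, summary,
                               config$out_dir)
  }
  list(results = results, national = national, sensitivity = sensitivity,
       summary = summary, files = files)
}

# deterministic writers; numerics rounded to 6 decimals so a written/re-read
# results table is bit-identical at the stated precision
write_run_outputs <- function(results, national, sensitivity, summary,
                              out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  res_path <- file.path(out_dir, "results.csv")
  out <- results
  num <- vapply(out, is.numeric, logical(1))
  out[num] <- lapply(out[num], round, digits = 6)
  utils::write.csv(out, res_path, row.names = FALSE)

  json_path <- file.path(out_dir, "summary.json")
  jsonlite::write_json(
    list(seed = summary$seed, config_hash = summary$config_hash,
         horizon_years = summary$horizon_years,
         national = national,
         percent_annual_death_reduction =
           summary$percent_annual_death_reduction),
    json_path, auto_unbox = TRUE, digits = NA)

  report_path <- file.path(out_dir, "report.txt")
  writeLines(format_report(results, national, sensitivity), report_path)

  log_path <- file.path(out_dir, "run_log.json")
  jsonlite::write_json(
    list(seed = summary$seed, config_hash = summary$config_hash,
         timestamp = format(Sys.time(), tz = "UTC")),
    log_path, auto_unbox = TRUE)
  message(sprintf("run complete: seed %d, config hash %s",
                  summary$seed, summary$config_hash))
  c(results = res_path, summary = json_path, report = report_path,
    log = log_path)
}

# plain-text table mirroring the headline lives-saved-by-segment layout
format_report <- function(results, national, sensitivity = NULL) {
  lines <- c("Quality-impact model: lives saved per horizon", "")
  if (nrow(results) == 0L) {
    return(c(lines, "(no scenarios requested)"))
  }
  fmt_persons <- function(x) {
    ifelse(is.na(x), "n/a", formatC(round_half_up(x), format = "d",
                                    big.mark = ","))
  }
  for (m in unique(results$measure)) {
    lines <- c(lines, sprintf("== %s ==", m))
    block <- results[results$measure == m, , drop = FALSE]
    nat <- national[national$measure == m, , drop = FALSE]
    for (sc in unique(block$scenario)) {
      b <- block[block$scenario == sc, , drop = FALSE]
      lines <- c(lines, sprintf("-- scenario %s --", sc))
      for (i in seq_len(nrow(b))) {
        note <- if (nzchar(b$note[i])) sprintf("  [%s]", b$note[i]) else ""
        lines <- c(lines, sprintf(
          "  %-16s gain %14s  lives %10s  events %10s%s",
          b$segment[i], fmt_persons(b$numerator_gain[i]),
          fmt_persons(b$lives_saved[i]), fmt_persons(b$events_averted[i]),
          note))
      }
      n <- nat[nat$scenario == sc, , drop = FALSE]
      if (nrow(n)) {
        lines <- c(lines, sprintf(
          "  %-16s gain %14s  lives %10s  events %10s",
          "National", fmt_persons(n$numerator_gain),
          fmt_persons(n$lives_saved), fmt_persons(n$events_averted)))
      }
    }
    lines <- c(lines, "")
  }
  if (!is.null(sensitivity) && nrow(sensitivity)) {
    lines <- c(lines, "== sensitivity (lives saved vs p66 baseline) ==")
    for (i in seq_len(nrow(sensitivity))) {
      lines <- c(lines, sprintf(
        "  %s %s %-24s baseline %8.0f  variant %8.0f  change %+.1f%%",
        sensitivity$measure[i], sensitivity$segment[i],
        sensitivity$label[i], sensitivity$baseline_lives[i],
        sensitivity$variant_lives[i], sensitivity$relative_change[i]))
    }
  }
  lines
}

#' Summarize benchmark distributions across segments
#'
#' Reports the global minimum and maximum of all percentile scores, each
#' segment's performance spread (mean of the 90th-minus-25th-percentile
#' range over its available measures), and which segment shows the widest
#' and narrowest spread among segments reporting both measures.
#'
#' @param tables list of [benchmark_table()]s, e.g. from
#'   [load_benchmark_tables()].
#' @return list with `min_score`, `max_score`, `ranges` (tibble: `segment`,
#'   `n_measures`, `mean_range`), `widest_segment`, `narrowest_segment`.
#' @export
table1_summary <- function(tables) {
  stopifnot(length(tables) >= 1L)
  all_scores <- unlist(lapply(tables, function(t) t$scores))
  segs <- unique(vapply(tables, function(t) t$segment, character(1)))
  ranges <- do.call(rbind, lapply(segs, function(seg) {
    seg_tabs <- Filter(function(t) t$segment == seg, tables)
    spreads <- vapply(seg_tabs,
                      function(t) unname(t$scores["90"] - t$scores["25"]),
                      numeric(1))
    tibble::tibble(segment = seg, n_measures = length(seg_tabs),
                   mean_range = mean(spreads))
  }))
  n_measures_total <- length(unique(vapply(tables,
                                           function(t) t$measure_id,
                                           character(1))))
  full <- ranges[ranges$n_measures == n_measures_total, , drop = FALSE]
  if (nrow(full) == 0L) full <- ranges
  list(
    min_score = min(all_scores),
    max_score = max(all_scores),
    ranges = ranges,
    widest_segment = full$segment[which.max(full$mean_range)],
    narrowest_segment = full$segment[which.min(full$mean_range)]
  )
}
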