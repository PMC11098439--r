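# Shared fixture helpers: everything is built in code or read from the
# package's shipped plain-text extdata.

bench_csv <- qi_example("benchmarks_2019.csv")
pop_csv <- qi_example("population_synthetic.csv")
prev_csv <- qi_example("prevalence_synthetic.csv")

medicare_crc <- function() load_benchmark_table(bench_csv, "crc_screening", "Medicare")
ca_bp <- function() load_benchmark_table(bench_csv, "bp_control", "CA-Marketplace")
all_tables <- function() load_benchmark_tables(bench_csv)

# six plans parked exactly at a table's bin assumed scores, with enrollment
# proportional to the bin weights (cross-module equivalence fixture)
plans_at_bin_scores <- function(table, weight_rule, total = 1e6) {
  bins <- make_bins(table, weight_rule)
  plan_roster(tibble::tibble(
    plan_id = paste0("p", seq_len(nrow(bins))),
    segment = table$segment,
    enrollment = bins$population_weight * total,
    score = bins$assumed_score
  ))
}
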