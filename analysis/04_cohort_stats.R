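#!/usr/bin/env Rscript
# Step 4 — cohort statistics.
#
# Per-variant carrier frequencies, aggregate carrier counts, and the
# Pearson chi-square comparison (no continuity correction) of carrier
# prevalence between cases and controls.

suppressPackageStartupMessages(library(mttscreen))

calls <- read.delim("results/calls.tsv")
classified <- read.delim("results/classified.tsv")

report <- aggregate_report(calls, n_cases = 352L, n_controls = 376L,
                           classified)
jsonlite::write_json(report, "results/stats.json", auto_unbox = TRUE,
                     digits = NA, pretty = TRUE)

message("carriers: ", report$case_carriers, "/", report$n_cases,
        " cases vs ", report$control_carriers, "/", report$n_controls,
        " controls")
message("variant-free: ", report$variant_free_cases, " cases, ",
        report$variant_free_controls, " controls")
message(sprintf("chi-square = %.3f (df 1), p = %.4f", report$chi2,
                report$p_value))
message("known-mutation carrier frequency: ", report$known_case_freq,
        "% of cases")
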