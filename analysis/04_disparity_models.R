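#!/usr/bin/env Rscript
# Disparity statistics on the labeled corpus: per-race contingency with
# relative changes, chi-square, fixed vs clinician-random-intercept logistic
# models with likelihood comparison, and the adjusted visit-time regression.

library(judgmentlang)

corpus <- read_corpus("results/corpus")
labels_csv <- utils::read.csv("results/labels.csv", colClasses = c("character", "logical", "integer"))
results <- dplyr::inner_join(
  tibble::as_tibble(labels_csv),
  corpus$notes[, c("note_id", "patient_id", "clinician_id", "visit_minutes")],
  by = "note_id")

ct <- build_contingency(results, corpus$patients, reference = "White")
chi <- chi_square_test(ct)
cat("contingency by race/ethnicity:\n")
print(as.data.frame(ct)[, c("group", "n_notes", "n_positive",
                            "pct_positive", "relative_change_vs_ref")])
cat(sprintf("chi-square: X2 = %.1f, df = %d, p = %.3g\n",
            chi$statistic, chi$df, chi$p_value))

df <- dplyr::inner_join(results, corpus$patients, by = "patient_id")
fixed <- fit_logistic(df)
mixed <- fit_mixed_logistic(df)
cmp <- compare_models(fixed, mixed)
cat(sprintf("fixed ll = %.1f; mixed ll = %.1f (clinician SD = %.3f)\n",
            cmp$ll_fixed, cmp$ll_mixed, mixed$re_sd))
cat(sprintf("LRT = %.1f, boundary-mixture p = %.3g; relative ll drop without RE = %.1f%%\n",
            cmp$lrt_statistic, cmp$p_value, cmp$relative_ll_change))

lin <- fit_linear_visit_time(df)
means <- group_mean_difference(df)
cat(sprintf("visit time: positive mean %.1f min, negative mean %.1f min, gap %.1f min\n",
            means$mean_positive, means$mean_negative, means$difference))
cat(sprintf("adjusted decrement per judgment word: %.2f min (95%% CI %.2f-%.2f)\n",
            lin$decrement_per_word, lin$decrement_ci[1], lin$decrement_ci[2]))

rep_tbl <- report_table(ct, fixed, mixed)
write_report(rep_tbl, "results")
cat("wrote results/report.csv and results/report.md\n")
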