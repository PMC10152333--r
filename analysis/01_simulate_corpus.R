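#!/usr/bin/env Rscript
# Simulate the study corpus: a synthetic home-health cohort with known
# judgment-language structure (per-race rates, clinician variation, and the
# visit-time decrement), written to results/corpus/ for the later stages.

library(judgmentlang)

seed <- 20260927L
cfg <- corpus_config(n_patients = 10000L, seed = seed)
corpus <- generate_corpus(cfg)

dir.create("results", showWarnings = FALSE)
write_corpus(corpus, "results/corpus")

rates <- tapply(corpus$truth$is_positive,
                corpus$patients$race_ethnicity[match(corpus$notes$patient_id,
                                                     corpus$patients$patient_id)],
                mean)
cat(sprintf("simulated %d patients, %d notes (mean %.1f chars)\n",
            nrow(corpus$patients), nrow(corpus$notes),
            mean(nchar(corpus$notes$text))))
cat("planted positive-note rate by race (marginal over clinician effects):\n")
print(round(100 * rates, 2))
cat(sprintf("mean visit length: %.1f min\n", mean(corpus$notes$visit_minutes)))
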