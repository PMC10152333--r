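#!/usr/bin/env Rscript
# Label every note for judgment language with the rule-based matcher
# (attribution + negation exclusions) and evaluate against the generator's
# ground truth.

library(judgmentlang)

corpus <- read_corpus("results/corpus")
lexicon <- load_lexicon("results/lexicon.json")
matcher <- compile_matcher(lexicon)

labels <- label_corpus(matcher, corpus$notes)
s <- labels$summary
cat(sprintf("%d/%d notes positive (%.1f%%); %d/%d patients with any judgment language (%.1f%%)\n",
            s$n_positive, s$n_notes, 100 * s$n_positive / s$n_notes,
            s$n_patients_positive, s$n_patients,
            100 * s$n_patients_positive / s$n_patients))

truth <- corpus$truth$is_positive[match(labels$results$note_id, corpus$truth$note_id)]
pred <- labels$results$is_positive
cat(sprintf("vs ground truth: sensitivity %.4f, specificity %.4f; %d candidate matches excluded\n",
            sum(pred & truth) / sum(truth), sum(!pred & !truth) / sum(!truth),
            sum(labels$results$n_excluded)))

utils::write.csv(
  data.frame(note_id = labels$results$note_id,
             is_positive = labels$results$is_positive,
             n_judgment_words = labels$results$n_judgment_words),
  "results/labels.csv", row.names = FALSE)
cat("wrote results/labels.csv\n")
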