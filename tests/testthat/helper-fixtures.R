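# Shared fixtures, generated once per test run and cached.

.fixture_env <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .fixture_env)) {
    assign(name, force(expr), envir = .fixture_env)
  }
  get(name, envir = .fixture_env)
}

small_corpus <- function() {
  cached("small_corpus", generate_corpus(corpus_config(400, seed = 101L)))
}

small_labels <- function() {
  cached("small_labels", {
    label_corpus(compile_matcher(default_lexicon()), small_corpus()$notes)
  })
}

# Large corpora used by the acceptance-grade checks.
big_corpus_sd0 <- function() {
  cached("big_corpus_sd0",
         generate_corpus(corpus_config(30000, clinician_re_sd = 0, seed = 2024L)))
}

big_corpus_default <- function() {
  cached("big_corpus_default",
         generate_corpus(corpus_config(10000, seed = 2025L)))
}

big_labels_default <- function() {
  cached("big_labels_default", {
    label_corpus(compile_matcher(default_lexicon()), big_corpus_default()$notes)
  })
}

table2_counts <- function() {
  tibble::tibble(
    group = c("White", "Asian", "Hispanic", "Black"),
    n_patients = c(19826L, 3921L, 10503L, 10969L),
    n_notes = c(107626L, 22548L, 66282L, 65628L),
    n_positive = c(10206L, 1756L, 7167L, 7010L)
  )
}
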