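#' Curated example visit notes with annotated judgment language
#'
#' Eleven short home-health visit notes, each containing judgment language,
#' with the annotated judgment terms (as printed, sometimes inflected) and
#' their canonical lexicon terms. Used as matcher fixtures: every note is
#' expected to be labeled positive with exactly the annotated canonical
#' terms.
#'
#' @return tibble with columns `text`, `annotated_terms` (list),
#'   `canonical_terms` (list), `n_occurrences`.
#' @export
judgment_examples <- function() {
  path <- system.file("extdata", "example_notes.json", package = "judgmentlang",
                      mustWork = TRUE)
  raw <- jsonlite::fromJSON(paste(readLines(path, encoding = "UTF-8", warn = FALSE),
                                  collapse = "\n"),
                            simplifyVector = FALSE)
  tibble::tibble(
    text = vapply(raw, function(r) r$text, ""),
    annotated_terms = lapply(raw, function(r) unlist(r$annotated_terms)),
    canonical_terms = lapply(raw, function(r) unlist(r$canonical_terms)),
    n_occurrences = vapply(raw, function(r) as.integer(r$n_occurrences), 0L)
  )
}

#' Exemplar provider-attributed phrases that must not match
#'
#' Three clinician-subject uses of judgment verbs that the attribution rule
#' excludes, plus a patient-subject counterexample that must remain positive.
#'
#' @return list with `excluded` (character vector) and `retained` (character
#'   scalar).
#' @export
attribution_exemplars <- function() {
  list(
    excluded = c(
      "vn convinced pt to accept home health aide.",
      "cardiologist stated the medication plan is unchanged.",
      "primary care insisted on repeat labs this week."
    ),
    retained = "pt also insisted vn to remove left foot dressing however no wound order suggested to do so."
  )
}
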