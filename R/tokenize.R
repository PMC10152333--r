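# Tokenization shared by the embedding trainer and the matcher.
#
# Lowercased word tokens; clinical abbreviations with internal periods
# ("d.m.", "h.f.") are kept as single tokens; other punctuation is stripped.

TOKEN_PATTERN <- "(?:[a-z0-9]+\\.){2,}|[a-z0-9]+(?:'[a-z0-9]+)*"

#' Tokenize a single note text
#'
#' @param text a character scalar (may be empty).
#' @return a character vector of lowercase tokens; `character(0)` for empty
#'   input. Abbreviations written with internal periods (e.g. "d.m.") are
#'   kept as single tokens.
#' @export
tokenize <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  tokenize_meta(text)[[1L]]$token
}

# Vectorized tokenizer with character offsets and sentence ids. A sentence
# boundary falls between tokens whose separating text contains ".", "!", "?"
# or ";"; periods consumed inside abbreviation tokens do not split.
tokenize_meta <- function(texts) {
  low <- stringi::stri_trans_tolower(texts)
  locs <- stringi::stri_locate_all_regex(low, TOKEN_PATTERN, omit_no_match = TRUE)
  toks <- stringi::stri_extract_all_regex(low, TOKEN_PATTERN, omit_no_match = TRUE)
  lapply(seq_along(texts), function(i) {
    tk <- toks[[i]]
    if (length(tk) == 0L || is.na(tk[1L])) {
      return(list(token = character(), start = integer(), end = integer(),
                  sentence = integer()))
    }
    loc <- locs[[i]]
    m <- length(tk)
    if (m > 1L) {
      gaps <- stringi::stri_sub(low[i], loc[-m, 2L] + 1L, loc[-1L, 1L] - 1L)
      brk <- stringi::stri_detect_regex(gaps, "[.!?;]")
      sent <- cumsum(c(1L, as.integer(brk)))
    } else {
      sent <- 1L
    }
    list(token = tk, start = as.integer(loc[, 1L]), end = as.integer(loc[, 2L]),
         sentence = sent)
  })
}

#' Tokenize a corpus of notes
#'
#' @param texts character vector of note texts.
#' @return list of class `tokenized_corpus` with `tokens` (list of token
#'   vectors, one per note) and `vocabulary` (tibble `token`, `n` with corpus
#'   frequencies).
#' @export
tokenize_corpus <- function(texts) {
  stopifnot(is.character(texts))
  toks <- stringi::stri_extract_all_regex(
    stringi::stri_trans_tolower(texts), TOKEN_PATTERN, omit_no_match = TRUE)
  toks <- lapply(toks, function(x) x[!is.na(x)])
  flat <- unlist(toks, use.names = FALSE)
  vocab <- if (length(flat)) {
    tab <- table(flat)
    tibble::tibble(token = names(tab), n = as.integer(tab))
  } else {
    tibble::tibble(token = character(), n = integer())
  }
  structure(list(tokens = toks, vocabulary = vocab), class = "tokenized_corpus")
}
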