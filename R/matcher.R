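#' Compile a judgment lexicon into a token matcher
#'
#' The matcher recognizes every surface form of the lexicon at word
#' boundaries (token-level equality, so "claims" never fires inside
#' "claimstone"), case-insensitively, including multi-token split forms
#' ("clai med"). Two exclusion rules are applied per candidate match, both
#' scoped to the match's sentence:
#'
#' * provider attribution: a provider cue is the nearest preceding subject
#'   cue within `attribution_window` tokens and no patient/family cue is
#'   nearer ("cardiologist stated", "vn convinced pt");
#' * negation: a negation cue occurs within the window before the match
#'   ("no insistence noted"). Patient-subject denial of clinical content
#'   ("pt vehemently denies this") is not excluded.
#'
#' @param lexicon a `judgment_lexicon` (must be nonempty).
#' @param attribution_window window `W` in tokens for both rules.
#' @param patient_cues patient/family subject cue tokens.
#' @return object of class `judgment_matcher`.
#' @export
compile_matcher <- function(lexicon, attribution_window = 5L,
                            patient_cues = default_patient_cues()) {
  stopifnot(inherits(lexicon, "judgment_lexicon"))
  surf <- lexicon_surfaces(lexicon)
  if (nrow(surf) == 0L) stop("cannot compile a matcher from an empty lexicon", call. = FALSE)
  if (attribution_window < 1L) stop("`attribution_window` must be >= 1", call. = FALSE)

  is_multi <- grepl(" ", surf$surface, fixed = TRUE)
  uni <- stats::setNames(surf$canonical[!is_multi], surf$surface[!is_multi])
  bi_parts <- strsplit(surf$surface[is_multi], " +")
  if (any(lengths(bi_parts) > 2L)) {
    stop("multi-token surface forms longer than two tokens are not supported",
         call. = FALSE)
  }
  bi <- if (any(is_multi)) {
    tibble::tibble(
      first = vapply(bi_parts, `[`, "", 1L),
      second = vapply(bi_parts, `[`, "", 2L),
      surface = surf$surface[is_multi],
      canonical = surf$canonical[is_multi]
    )
  } else {
    tibble::tibble(first = character(), second = character(),
                   surface = character(), canonical = character())
  }

  prov <- tolower(lexicon$provider_cues)
  prov_multi <- grepl(" ", prov, fixed = TRUE)
  prov_bi <- strsplit(prov[prov_multi], " +")
  pat <- tolower(patient_cues)
  overlap <- intersect(prov[!prov_multi], pat)
  if (length(overlap)) {
    stop("cue token(s) appear in both provider and patient lists: ",
         paste(overlap, collapse = ", "), call. = FALSE)
  }

  structure(
    list(uni = uni, bi = bi,
         provider_uni = prov[!prov_multi],
         provider_bi_first = vapply(prov_bi, `[`, "", 1L),
         provider_bi_second = vapply(prov_bi, `[`, "", 2L),
         patient_cues = pat,
         negation_cues = tolower(lexicon$negation_cues),
         window = as.integer(attribution_window)),
    class = "judgment_matcher"
  )
}

# Core single-note matching over pre-tokenized input (token vector, sentence
# ids). Returns the full match/exclusion detail.
match_tokens <- function(matcher, meta) {
  tk <- meta$token
  sent <- meta$sentence
  w <- matcher$window
  empty_m <- tibble::tibble(canonical = character(), surface = character(),
                            token_start = integer(), token_end = integer(),
                            char_start = integer(), char_end = integer())
  empty_x <- tibble::tibble(surface = character(), token_start = integer(),
                            token_end = integer(), reason = character())
  if (length(tk) == 0L) return(list(matches = empty_m, excluded = empty_x))

  # candidate occurrences
  uni_pos <- which(tk %in% names(matcher$uni))
  cand <- tibble::tibble(
    token_start = uni_pos, token_end = uni_pos,
    surface = tk[uni_pos],
    canonical = unname(matcher$uni[tk[uni_pos]])
  )
  if (nrow(matcher$bi) > 0L && length(tk) > 1L) {
    key <- paste(tk[-length(tk)], tk[-1L])
    bikey <- paste(matcher$bi$first, matcher$bi$second)
    hit <- which(key %in% bikey & sent[-length(tk)] == sent[-1L])
    if (length(hit)) {
      m <- match(key[hit], bikey)
      cand <- rbind(cand, tibble::tibble(
        token_start = hit, token_end = hit + 1L,
        surface = matcher$bi$surface[m],
        canonical = matcher$bi$canonical[m]
      ))
    }
  }
  if (nrow(cand) == 0L) return(list(matches = empty_m, excluded = empty_x))
  cand <- cand[order(cand$token_start), , drop = FALSE]

  # cue positions
  prov_flag <- tk %in% matcher$provider_uni
  if (length(matcher$provider_bi_first) && length(tk) > 1L) {
    bi_hit <- tk[-length(tk)] %in% matcher$provider_bi_first &
      tk[-1L] %in% matcher$provider_bi_second &
      sent[-length(tk)] == sent[-1L]
    # mark the bigram cue at its final token
    prov_flag[which(bi_hit) + 1L] <- TRUE
  }
  pat_flag <- tk %in% matcher$patient_cues
  neg_flag <- tk %in% matcher$negation_cues

  reason <- character(nrow(cand))
  for (r in seq_len(nrow(cand))) {
    s <- cand$token_start[r]
    win <- seq.int(max(1L, s - w), s - 1L)
    win <- win[sent[win] == sent[s]]
    if (length(win)) {
      dp <- if (any(prov_flag[win])) s - max(win[prov_flag[win]]) else NA_integer_
      dq <- if (any(pat_flag[win])) s - max(win[pat_flag[win]]) else NA_integer_
      if (!is.na(dp) && (is.na(dq) || dp < dq)) {
        reason[r] <- "provider_attribution"
      } else if (any(neg_flag[win])) {
        reason[r] <- "negation"
      }
    }
  }

  kept <- cand[reason == "", , drop = FALSE]
  matches <- tibble::tibble(
    canonical = kept$canonical, surface = kept$surface,
    token_start = kept$token_start, token_end = kept$token_end,
    char_start = meta$start[kept$token_start],
    char_end = meta$end[kept$token_end]
  )
  excl <- cand[reason != "", , drop = FALSE]
  excluded <- tibble::tibble(
    surface = excl$surface, token_start = excl$token_start,
    token_end = excl$token_end, reason = reason[reason != ""]
  )
  list(matches = matches, excluded = excluded)
}

#' Match a single note text
#'
#' @param matcher a compiled `judgment_matcher`.
#' @param text the note text (a character scalar; empty text gives a negative
#'   result).
#' @param note_id optional identifier carried into the result.
#' @return object of class `match_result`: `matches` (tibble with canonical
#'   term, surface form, token and character spans), `excluded` (tibble with
#'   surface, span and reason: `provider_attribution` or `negation`),
#'   `is_positive`, `n_judgment_words` (retained occurrences) and
#'   `distinct_terms` (canonical terms).
#' @export
match_note <- function(matcher, text, note_id = NA_character_) {
  stopifnot(inherits(matcher, "judgment_matcher"),
            is.character(text), length(text) == 1L)
  res <- match_tokens(matcher, tokenize_meta(text)[[1L]])
  structure(
    list(note_id = note_id, matches = res$matches, excluded = res$excluded,
         is_positive = nrow(res$matches) > 0L,
         n_judgment_words = nrow(res$matches),
         distinct_terms = sort(unique(res$matches$canonical))),
    class = "match_result"
  )
}

#' Label a corpus of notes
#'
#' Applies the matcher to every note. A patient is flagged positive iff at
#' least one of their notes is positive.
#'
#' @param matcher a compiled `judgment_matcher`.
#' @param notes tibble with `note_id`, `text` and (optionally) `patient_id`;
#'   duplicated `note_id`s are an error.
#' @return list with `results` (tibble: `note_id`, `patient_id`,
#'   `is_positive`, `n_judgment_words`, `distinct_terms` list-column,
#'   `n_excluded`), `matches` (long tibble of retained matches),
#'   `patient_summary` (tibble: `patient_id`, `has_any_judgment`) and
#'   `summary` (note/positive/patient counts).
#' @export
label_corpus <- function(matcher, notes) {
  stopifnot(inherits(matcher, "judgment_matcher"), is.data.frame(notes))
  if (anyDuplicated(notes$note_id)) {
    stop("duplicate note_id(s): ",
         paste(utils::head(unique(notes$note_id[duplicated(notes$note_id)]), 5L),
               collapse = ", "), call. = FALSE)
  }
  metas <- tokenize_meta(notes$text)

  # fast path: only notes containing a candidate token go through full matching
  all_surf_uni <- names(matcher$uni)
  need <- vapply(metas, function(m) {
    any(m$token %in% all_surf_uni) ||
      (nrow(matcher$bi) > 0L && any(m$token %in% matcher$bi$first))
  }, NA)

  n <- nrow(notes)
  n_words <- integer(n)
  n_excl <- integer(n)
  terms <- vector("list", n)
  terms[!need] <- list(character())
  match_rows <- vector("list", n)
  for (i in which(need)) {
    res <- match_tokens(matcher, metas[[i]])
    n_words[i] <- nrow(res$matches)
    n_excl[i] <- nrow(res$excluded)
    terms[[i]] <- sort(unique(res$matches$canonical))
    if (n_words[i] > 0L) {
      match_rows[[i]] <- cbind(note_id = notes$note_id[i], res$matches)
    }
  }

  patient_id <- if ("patient_id" %in% names(notes)) notes$patient_id else NA_character_
  results <- tibble::tibble(
    note_id = notes$note_id,
    patient_id = patient_id,
    is_positive = n_words > 0L,
    n_judgment_words = n_words,
    distinct_terms = terms,
    n_excluded = n_excl
  )
  matches <- if (any(n_words > 0L)) {
    tibble::as_tibble(do.call(rbind, match_rows[n_words > 0L]))
  } else {
    tibble::tibble(note_id = character(), canonical = character(),
                   surface = character(), token_start = integer(),
                   token_end = integer(), char_start = integer(),
                   char_end = integer())
  }
  patient_summary <- if ("patient_id" %in% names(notes)) {
    dplyr::summarise(dplyr::group_by(results, .data$patient_id),
                     has_any_judgment = any(.data$is_positive), .groups = "drop")
  } else {
    tibble::tibble(patient_id = character(), has_any_judgment = logical())
  }
  list(
    results = results,
    matches = matches,
    patient_summary = patient_summary,
    summary = list(
      n_notes = n,
      n_positive = sum(results$is_positive),
      n_patients = nrow(patient_summary),
      n_patients_positive = sum(patient_summary$has_any_judgment)
    )
  )
}
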