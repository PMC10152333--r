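LEXICON_SCHEMA_VERSION <- "1.0"

#' Default provider (attribution) cue tokens
#'
#' Tokens that, as the nearest preceding subject cue, mark a judgment verb as
#' attributed to a clinician rather than the patient. Multi-token cues
#' ("primary care") are written with a space. The original study's inventories
#' are unpublished; these are configurable defaults.
#' @return character vector of cues.
#' @export
default_provider_cues <- function() {
  c("vn", "rn", "md", "pcp", "dr", "cardiologist", "doctor", "nurse",
    "therapist", "physician", "pharmacist", "primary care")
}

#' Default patient/family subject cue tokens
#' @return character vector of cues.
#' @export
default_patient_cues <- function() {
  c("pt", "pts", "patient", "patients", "he", "she", "husband", "wife",
    "caregiver", "son", "daughter", "family", "spouse")
}

#' Default negation cue tokens
#'
#' Cue-and-scope negation: a judgment term within the scope window after one
#' of these cues is excluded ("no insistence noted"). Patient-subject denial
#' of clinical content ("pt vehemently denies this") is not negation of the
#' judgment term and is retained.
#' @return character vector of cues.
#' @export
default_negation_cues <- function() {
  c("no", "not", "never", "without")
}

#' The seed judgment vocabulary
#'
#' The literature-derived starting lexicon of words by which a documenting
#' clinician distances themself from a patient's statements.
#' @return character vector of the five seed terms.
#' @export
default_seeds <- function() {
  c("adamant", "apparently", "claims", "insists", "states")
}

#' Construct a judgment lexicon
#'
#' @param seeds character vector of seed terms (canonical).
#' @param variants named list: canonical term -> character vector of surface
#'   forms (inflections, misspellings, split-token forms such as "clai med").
#'   Canonicals not among the seeds are allowed (novel expansion terms).
#' @param provider_cues,negation_cues cue token lists for the matcher's
#'   exclusion rules.
#' @param version schema version string.
#' @return object of class `judgment_lexicon`.
#' @export
judgment_lexicon <- function(seeds = default_seeds(),
                             variants = list(),
                             provider_cues = default_provider_cues(),
                             negation_cues = default_negation_cues(),
                             version = LEXICON_SCHEMA_VERSION) {
  seeds <- unique(tolower(seeds))
  variants <- lapply(variants, function(x) unique(tolower(x)))
  if (length(variants) && is.null(names(variants))) {
    stop("`variants` must be a named list keyed by canonical term", call. = FALSE)
  }
  names(variants) <- tolower(names(variants))
  # pairwise disjoint surface sets: no surface (canonicals count as their own
  # surface) may map to two different canonical terms
  canon <- union(seeds, names(variants))
  surf <- c(canon, unlist(variants, use.names = FALSE))
  owner <- c(canon, rep(names(variants), lengths(variants)))
  keep <- !duplicated(paste(surf, owner))
  surf <- surf[keep]; owner <- owner[keep]
  if (anyDuplicated(surf)) {
    dup <- unique(surf[duplicated(surf)])
    stop("surface form(s) assigned to more than one canonical term: ",
         paste(dup, collapse = ", "), call. = FALSE)
  }
  structure(
    list(seeds = seeds, variants = variants,
         provider_cues = unique(tolower(provider_cues)),
         negation_cues = unique(tolower(negation_cues)),
         version = version),
    class = "judgment_lexicon"
  )
}

#' Canonical terms of a lexicon
#' @param lexicon a `judgment_lexicon`.
#' @return character vector: seeds plus novel canonicals from the variants.
#' @export
lexicon_canonicals <- function(lexicon) {
  union(lexicon$seeds, names(lexicon$variants))
}

#' Surface-form table of a lexicon
#' @param lexicon a `judgment_lexicon`.
#' @return tibble with columns `surface`, `canonical` (each canonical is its
#'   own surface form too).
#' @export
lexicon_surfaces <- function(lexicon) {
  canon <- lexicon_canonicals(lexicon)
  base <- tibble::tibble(surface = canon, canonical = canon)
  var <- if (length(lexicon$variants)) {
    tibble::tibble(
      surface = unlist(lexicon$variants, use.names = FALSE),
      canonical = rep(names(lexicon$variants), lengths(lexicon$variants))
    )
  } else {
    tibble::tibble(surface = character(), canonical = character())
  }
  out <- rbind(base, var)
  out[!duplicated(out$surface), , drop = FALSE]
}

#' The package's default expanded judgment lexicon
#'
#' The five seed terms plus the reviewed expansion vocabulary: novel
#' judgment verbs ("convinced", "vehemently", "believes", "admits"),
#' inflections (e.g. "claimed", "insisted", "adamantly") and observed
#' misspellings ("claimes", "clamed", the split-token "clai med",
#' "aparently").
#' @return a `judgment_lexicon`.
#' @export
default_lexicon <- function() {
  judgment_lexicon(
    seeds = default_seeds(),
    variants = list(
      adamant = c("adamantly"),
      apparently = c("aparently"),
      claims = c("claim", "claimed", "claiming", "claimes", "clamed", "clai med"),
      insists = c("insist", "insisted", "insisting"),
      states = c("stated"),
      convinced = character(),
      vehemently = character(),
      believes = c("believed"),
      admits = character()
    )
  )
}

#' Merge two reviewers' candidate decision sets
#'
#' @param a,b data frames with columns `candidate`, `canonical`, `decision`
#'   (`"accept"` or `"reject"`).
#' @return list with `decisions` (the agreed union) and `conflicts` (tibble of
#'   candidates with contradictory decisions or canonical assignments,
#'   flagged for adjudication rather than silently resolved).
#' @export
merge_decisions <- function(a, b) {
  both <- tibble::as_tibble(rbind(as.data.frame(a), as.data.frame(b)))
  both <- unique(both)
  n_by_cand <- table(both$candidate)
  conflicted <- names(n_by_cand)[n_by_cand > 1L]
  list(
    decisions = both[!both$candidate %in% conflicted, , drop = FALSE],
    conflicts = both[both$candidate %in% conflicted, , drop = FALSE]
  )
}

#' Expand a seed lexicon with reviewed embedding candidates
#'
#' Builds the final judgment lexicon from the seed terms and a set of
#' reviewer accept/reject decisions over embedding-derived candidates. Each
#' accepted candidate is assigned to a canonical term: the seed whose
#' neighborhood produced it, or a new canonical for novel judgment verbs.
#'
#' @param seeds character vector of seed terms.
#' @param decisions data frame with columns `candidate`, `canonical`,
#'   `decision` (`"accept"`/`"reject"`) and optionally `manual` (logical;
#'   marks explicit manual additions exempt from the vocabulary check).
#' @param model optional `embedding_model`; when given, accepted non-manual
#'   candidates must be in its vocabulary.
#' @param provider_cues,negation_cues cue lists passed through to the lexicon.
#' @return a `judgment_lexicon`; rejected candidates are absent. A candidate
#'   accepted under two canonicals is a conflict error.
#' @export
expand_lexicon <- function(seeds, decisions = NULL, model = NULL,
                           provider_cues = default_provider_cues(),
                           negation_cues = default_negation_cues()) {
  if (is.null(decisions) || nrow(decisions) == 0L) {
    return(judgment_lexicon(seeds, list(), provider_cues, negation_cues))
  }
  decisions <- tibble::as_tibble(decisions)
  stopifnot(all(c("candidate", "canonical", "decision") %in% names(decisions)))
  if (!all(decisions$decision %in% c("accept", "reject"))) {
    stop("`decision` must be 'accept' or 'reject'", call. = FALSE)
  }
  acc <- decisions[decisions$decision == "accept", , drop = FALSE]
  acc$candidate <- tolower(acc$candidate)
  acc$canonical <- tolower(acc$canonical)
  multi <- tapply(acc$canonical, acc$candidate, function(x) length(unique(x)))
  if (any(multi > 1L)) {
    stop("conflict: candidate(s) accepted under more than one canonical term: ",
         paste(names(multi)[multi > 1L], collapse = ", "), call. = FALSE)
  }
  acc <- unique(acc[, intersect(c("candidate", "canonical", "manual"), names(acc))])
  if (!is.null(model)) {
    manual <- if ("manual" %in% names(acc)) isTRUE_vec(acc$manual) else rep(FALSE, nrow(acc))
    # multi-token surface forms are matched at the token-sequence level and
    # need not be single vocabulary entries
    single <- !grepl(" ", acc$candidate, fixed = TRUE)
    missing <- acc$candidate[single & !manual &
                               !acc$candidate %in% rownames(model$vectors)]
    if (length(missing)) {
      stop("accepted candidate(s) not in model vocabulary and not marked manual: ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
  }
  canon <- unique(acc$canonical)
  variants <- lapply(stats::setNames(canon, canon), function(cn) {
    setdiff(acc$candidate[acc$canonical == cn], cn)
  })
  judgment_lexicon(seeds, variants, provider_cues, negation_cues)
}

isTRUE_vec <- function(x) !is.na(x) & as.logical(x)

#' Save a judgment lexicon as JSON
#' @param lexicon a `judgment_lexicon`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
save_lexicon <- function(lexicon, path) {
  stopifnot(inherits(lexicon, "judgment_lexicon"))
  payload <- list(
    version = lexicon$version,
    seeds = lexicon$seeds,
    variants = lexicon$variants,
    provider_cues = lexicon$provider_cues,
    negation_cues = lexicon$negation_cues
  )
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(as.character(jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA)),
             con, useBytes = FALSE)
  invisible(path)
}

#' Load a judgment lexicon from JSON
#' @param path file written by [save_lexicon()].
#' @return a `judgment_lexicon`; errors on a missing file or an incompatible
#'   schema version.
#' @export
load_lexicon <- function(path) {
  if (!file.exists(path)) stop("lexicon file not found: ", path, call. = FALSE)
  payload <- jsonlite::fromJSON(readLines(path, encoding = "UTF-8", warn = FALSE),
                                simplifyVector = TRUE)
  if (is.null(payload$version) ||
      strsplit(payload$version, ".", fixed = TRUE)[[1]][1] !=
        strsplit(LEXICON_SCHEMA_VERSION, ".", fixed = TRUE)[[1]][1]) {
    stop(sprintf("lexicon schema mismatch: file version '%s', supported '%s'",
                 payload$version %||% "<missing>", LEXICON_SCHEMA_VERSION),
         call. = FALSE)
  }
  variants <- lapply(payload$variants, as.character)
  judgment_lexicon(payload$seeds, variants, payload$provider_cues,
                   payload$negation_cues, version = payload$version)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
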