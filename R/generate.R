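#' Generate a synthetic patient cohort and clinician pool
#'
#' Samples patients (race/ethnicity, gender) from the configured
#' distributions and a clinician pool with i.i.d. Normal(0, `clinician_re_sd`^2)
#' random intercepts on the logit scale. Fully reproducible from
#' `config$seed`.
#'
#' @param config a [corpus_config()].
#' @return a list of class `cohort` with elements `patients` (tibble:
#'   `patient_id`, `race_ethnicity`, `gender`) and `clinicians` (tibble:
#'   `clinician_id`, `intercept`).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "corpus_config"))
  set.seed(config$seed)
  n <- config$n_patients
  races <- names(config$race_probs)
  genders <- names(config$gender_probs)
  patients <- tibble::tibble(
    patient_id = sprintf("P%07d", seq_len(n)),
    race_ethnicity = if (n > 0) sample(races, n, replace = TRUE, prob = config$race_probs) else character(),
    gender = if (n > 0) sample(genders, n, replace = TRUE, prob = config$gender_probs) else character()
  )
  clinicians <- tibble::tibble(
    clinician_id = sprintf("C%04d", seq_len(config$n_clinicians)),
    intercept = stats::rnorm(config$n_clinicians, 0, config$clinician_re_sd)
  )
  structure(list(patients = patients, clinicians = clinicians), class = "cohort")
}

#' Generate synthetic visit notes with ground-truth judgment labels
#'
#' Per patient, the note count is 1-shifted Poisson with the configured mean.
#' Note text is assembled from a bank of neutral home-care sentences to
#' approximately `note_length_chars_mean` characters. A note is positive with
#' probability `plogis(qlogis(rate[race]) + clinician intercept)`; positive
#' notes embed >= 1 judgment phrase (patient-subject framing, misspellings at
#' `misspelling_rate`), negative notes embed a provider-attributed judgment
#' verb at `confounder_rate`. Visit minutes are
#' `visit_base_min - visit_decrement_per_word_min * words + noise`, floored
#' at 5.
#'
#' @param cohort a `cohort` from [generate_cohort()]; must be nonempty.
#' @param config the same [corpus_config()].
#' @return list with `notes` (tibble: `note_id`, `patient_id`,
#'   `clinician_id`, `text`, `visit_minutes`) and `truth` (tibble: `note_id`,
#'   `is_positive`, `planted_terms`, `planted_confounders`; the last two are
#'   list-columns of tibbles with `term`, `start`, `end` character spans).
#' @export
generate_notes <- function(cohort, config) {
  stopifnot(inherits(config, "corpus_config"))
  if (!inherits(cohort, "cohort") || nrow(cohort$patients) == 0L) {
    stop("`cohort` must be a nonempty cohort", call. = FALSE)
  }
  set.seed(stage_seed(config$seed, 1L))

  pat <- cohort$patients
  cli <- cohort$clinicians
  n_pat <- nrow(pat)

  n_notes_per_pat <- 1L + stats::rpois(n_pat, config$notes_per_patient_mean - 1)
  n <- sum(n_notes_per_pat)
  pat_idx <- rep.int(seq_len(n_pat), n_notes_per_pat)

  cli_idx <- sample.int(nrow(cli), n, replace = TRUE)
  race <- pat$race_ethnicity[pat_idx]
  p_pos <- unname(stats::plogis(stats::qlogis(config$judgment_rate_by_race[race]) +
                                  cli$intercept[cli_idx]))
  is_pos <- stats::runif(n) < p_pos
  words <- integer(n)
  if (any(is_pos)) {
    words[is_pos] <- 1L + stats::rpois(sum(is_pos), config$words_per_positive_note_mean - 1)
  }
  has_conf <- !is_pos & stats::runif(n) < config$confounder_rate

  # neutral sentence scaffolding
  bank <- neutral_sentence_bank
  mean_sent_chars <- mean(nchar(bank)) + 1  # +1 for joining space
  target_sent <- config$note_length_chars_mean / mean_sent_chars
  n_sent <- pmin(20L, pmax(2L, as.integer(round(stats::rnorm(n, target_sent, 1)))))
  sent_ids <- sample.int(length(bank), sum(n_sent), replace = TRUE)
  sent_split <- split(bank[sent_ids], rep.int(seq_len(n), n_sent))

  canonicals <- names(judgment_sentence_templates)
  empty_spans <- tibble::tibble(term = character(), start = integer(), end = integer())

  texts <- character(n)
  planted <- vector("list", n)
  confound <- vector("list", n)
  plain <- !is_pos & !has_conf
  if (any(plain)) {
    texts[plain] <- vapply(sent_split[which(plain)], paste, "", collapse = " ")
  }
  planted[plain | has_conf] <- list(empty_spans)
  confound[plain | is_pos] <- list(empty_spans)

  build_note <- function(neutral, extra_sentences, extra_marks) {
    # insert extra sentences at random slots among the neutral ones, then
    # compute 1-based character spans of the marked substrings
    k <- length(extra_sentences)
    slots <- sort(sample.int(length(neutral) + 1L, k, replace = TRUE))
    all_s <- character(length(neutral) + k)
    pos_extra <- slots + seq_len(k) - 1L
    all_s[pos_extra] <- extra_sentences
    all_s[-pos_extra] <- neutral
    offsets <- c(0L, cumsum(nchar(all_s) + 1L))[seq_along(all_s)]
    starts <- offsets[pos_extra] + extra_marks$prefix_len + 1L
    list(
      text = paste(all_s, collapse = " "),
      spans = tibble::tibble(term = extra_marks$surface,
                             start = as.integer(starts),
                             end = as.integer(starts + nchar(extra_marks$surface) - 1L))
    )
  }

  for (i in which(is_pos)) {
    w <- words[i]
    canon <- sample(canonicals, w, replace = TRUE)
    surface <- vapply(unname(canon), function(cn) {
      mis <- planting_misspellings[[cn]]
      if (!is.null(mis) && stats::runif(1) < config$misspelling_rate) {
        sample(mis, 1L)
      } else {
        sample(planting_surface_forms[[cn]], 1L)
      }
    }, "")
    surface <- unname(surface)
    tmpl <- judgment_sentence_templates[canon]
    sentences <- vapply(seq_len(w), function(j) {
      paste0(tmpl[[j]][1], surface[j], tmpl[[j]][2])
    }, "")
    built <- build_note(sent_split[[i]], sentences,
                        list(surface = surface,
                             prefix_len = nchar(vapply(tmpl, `[`, "", 1L))))
    texts[i] <- built$text
    planted[[i]] <- built$spans
  }

  for (i in which(has_conf)) {
    cs <- sample(confounder_sentence_bank, 1L)
    built <- build_note(sent_split[[i]], cs,
                        list(surface = cs, prefix_len = 0L))
    texts[i] <- built$text
    confound[[i]] <- built$spans
  }

  visit <- pmax(5, config$visit_base_min -
                  config$visit_decrement_per_word_min * words +
                  stats::rnorm(n, 0, config$visit_noise_sd_min))

  note_id <- sprintf("N%08d", seq_len(n))
  notes <- tibble::tibble(
    note_id = note_id,
    patient_id = pat$patient_id[pat_idx],
    clinician_id = cli$clinician_id[cli_idx],
    text = texts,
    visit_minutes = visit
  )
  truth <- tibble::tibble(
    note_id = note_id,
    is_positive = is_pos,
    planted_terms = planted,
    planted_confounders = confound
  )
  list(notes = notes, truth = truth)
}

#' Generate a full synthetic corpus in one call
#'
#' Convenience wrapper around [generate_cohort()] and [generate_notes()].
#'
#' @param config a [corpus_config()].
#' @return list of class `note_corpus` with `patients`, `clinicians`,
#'   `notes`, `truth`.
#' @export
generate_corpus <- function(config) {
  cohort <- generate_cohort(config)
  if (nrow(cohort$patients) == 0L) {
    nt <- list(
      notes = tibble::tibble(note_id = character(), patient_id = character(),
                             clinician_id = character(), text = character(),
                             visit_minutes = double()),
      truth = tibble::tibble(note_id = character(), is_positive = logical(),
                             planted_terms = list(), planted_confounders = list())
    )
  } else {
    nt <- generate_notes(cohort, config)
  }
  structure(list(patients = cohort$patients, clinicians = cohort$clinicians,
                 notes = nt$notes, truth = nt$truth),
            class = "note_corpus")
}
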