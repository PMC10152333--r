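#' Configuration for the synthetic note-corpus generator
#'
#' Defines the study conditions the generator emulates: cohort composition,
#' per-race judgment-language rates, between-clinician variation, and the
#' visit-time model. Defaults reproduce the structure of a large urban
#' home-health cohort: ~6 visit notes per patient averaging ~298 characters,
#' race mix White/Black/Hispanic/Asian = 44/24/23/9%, per-race judgment-note
#' rates 9.5/10.7/10.8/7.8%, mean visit ~68 minutes with a 21-minute decrease
#' per judgment word.
#'
#' @param n_patients number of patients to simulate (>= 0).
#' @param notes_per_patient_mean mean notes per patient; counts are drawn from
#'   a 1-shifted Poisson so every patient has at least one note.
#' @param note_length_chars_mean target mean note length in characters.
#' @param race_probs named probabilities for White/Black/Hispanic/Asian; must
#'   sum to 1.
#' @param gender_probs named probabilities over gender levels; must sum to 1.
#' @param judgment_rate_by_race named per-race probability that a note
#'   contains judgment language (on the marginal scale when
#'   `clinician_re_sd = 0`; composed with the clinician intercept on the logit
#'   scale otherwise).
#' @param clinician_re_sd SD of the clinician random intercept on the logit
#'   scale (>= 0).
#' @param n_clinicians number of clinicians; each note is attributed to one
#'   clinician drawn uniformly.
#' @param visit_base_min baseline visit length in minutes.
#' @param visit_decrement_per_word_min minutes removed per planted judgment
#'   word.
#' @param visit_noise_sd_min SD of Gaussian visit-length noise in minutes;
#'   visits are floored at 5 minutes.
#' @param words_per_positive_note_mean mean planted judgment words per
#'   positive note (1-shifted Poisson; must be >= 1). The default 1.14
#'   reconciles a 70-minute baseline, 21-minute decrement and ~46-minute mean
#'   positive visit.
#' @param misspelling_rate probability a planted term uses a known
#'   misspelling.
#' @param confounder_rate probability a negative note carries a
#'   provider-attributed judgment verb (e.g. "cardiologist stated").
#' @param seed integer seed; all generator output is deterministic given the
#'   config.
#'
#' @return an object of class `corpus_config`.
#' @export
corpus_config <- function(n_patients,
                          notes_per_patient_mean = 6,
                          note_length_chars_mean = 298,
                          race_probs = c(White = 0.44, Black = 0.24,
                                         Hispanic = 0.23, Asian = 0.09),
                          gender_probs = c(F = 0.6, M = 0.4),
                          judgment_rate_by_race = c(White = 0.095, Black = 0.107,
                                                    Hispanic = 0.108, Asian = 0.078),
                          clinician_re_sd = 0.5,
                          n_clinicians = 200,
                          visit_base_min = 70,
                          visit_decrement_per_word_min = 21,
                          visit_noise_sd_min = 10,
                          words_per_positive_note_mean = 1.14,
                          misspelling_rate = 0.05,
                          confounder_rate = 0.05,
                          seed = 1L) {
  if (!is.numeric(n_patients) || length(n_patients) != 1L || n_patients < 0 ||
      n_patients != floor(n_patients)) {
    stop("configuration error: `n_patients` must be a nonnegative integer", call. = FALSE)
  }
  assert_prob_vector(race_probs, "race_probs")
  assert_sums_to_one(race_probs, "race_probs")
  assert_prob_vector(gender_probs, "gender_probs")
  assert_sums_to_one(gender_probs, "gender_probs")
  if (is.null(names(race_probs)) || is.null(names(gender_probs)) ||
      is.null(names(judgment_rate_by_race))) {
    stop("configuration error: probability vectors must be named", call. = FALSE)
  }
  if (!setequal(names(judgment_rate_by_race), names(race_probs))) {
    stop("configuration error: `judgment_rate_by_race` must be keyed by the race levels",
         call. = FALSE)
  }
  assert_prob_vector(judgment_rate_by_race, "judgment_rate_by_race")
  assert_prob_vector(misspelling_rate, "misspelling_rate")
  assert_prob_vector(confounder_rate, "confounder_rate")
  if (notes_per_patient_mean < 1) {
    stop("configuration error: `notes_per_patient_mean` must be >= 1", call. = FALSE)
  }
  if (words_per_positive_note_mean < 1) {
    stop("configuration error: `words_per_positive_note_mean` must be >= 1", call. = FALSE)
  }
  if (note_length_chars_mean <= 0) {
    stop("configuration error: `note_length_chars_mean` must be positive", call. = FALSE)
  }
  if (clinician_re_sd < 0 || visit_noise_sd_min < 0) {
    stop("configuration error: standard deviations must be nonnegative", call. = FALSE)
  }
  if (n_clinicians < 1 || n_clinicians != floor(n_clinicians)) {
    stop("configuration error: `n_clinicians` must be a positive integer", call. = FALSE)
  }

  structure(
    list(
      n_patients = as.integer(n_patients),
      notes_per_patient_mean = notes_per_patient_mean,
      note_length_chars_mean = note_length_chars_mean,
      race_probs = race_probs,
      gender_probs = gender_probs,
      judgment_rate_by_race = judgment_rate_by_race[names(race_probs)],
      clinician_re_sd = clinician_re_sd,
      n_clinicians = as.integer(n_clinicians),
      visit_base_min = visit_base_min,
      visit_decrement_per_word_min = visit_decrement_per_word_min,
      visit_noise_sd_min = visit_noise_sd_min,
      words_per_positive_note_mean = words_per_positive_note_mean,
      misspelling_rate = misspelling_rate,
      confounder_rate = confounder_rate,
      seed = as.integer(seed)
    ),
    class = "corpus_config"
  )
}
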