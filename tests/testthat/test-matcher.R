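test_that("matcher respects word boundaries, case, and split-token forms", {
  lex <- judgment_lexicon(seeds = "claims",
                          variants = list(claims = c("clai med")))
  m <- compile_matcher(lex)
  expect_true(match_note(m, "pt CLAIMS to feel fine")$is_positive)
  expect_false(match_note(m, "the claimstone path was icy")$is_positive)
  r <- match_note(m, "pt clai med relief of pain")
  expect_true(r$is_positive)
  expect_identical(r$matches$surface, "clai med")
  expect_false(match_note(m, "")$is_positive)
})

test_that("compiling an empty or inconsistent lexicon fails", {
  expect_error(compile_matcher(judgment_lexicon(seeds = character())), "empty")
  expect_error(judgment_lexicon(seeds = c("claims", "states"),
                                variants = list(claims = "stated",
                                                states = "stated")),
               "more than one canonical")
})

test_that("provider attribution excludes clinician-subject judgment verbs", {
  m <- compile_matcher(default_lexicon())
  ax <- attribution_exemplars()
  for (txt in ax$excluded) {
    r <- match_note(m, txt)
    expect_false(r$is_positive)
    expect_true(all(r$excluded$reason == "provider_attribution"))
  }
  expect_true(match_note(m, ax$retained)$is_positive)
  # nearest-cue-wins: patient cue closer than provider cue keeps the match
  r <- match_note(m, "rn notes pt claims pain is better")
  expect_true(r$is_positive)
})

test_that("negation cues within the window exclude the judgment term itself", {
  m <- compile_matcher(default_lexicon())
  r <- match_note(m, "pt was not adamant about the dressing routine")
  expect_false(r$is_positive)
  expect_identical(r$excluded$reason, "negation")
  # patient-subject denial of clinical content is retained
  expect_true(match_note(m, "pt vehemently denies this")$is_positive)
  # scope does not cross sentence boundaries
  expect_true(match_note(m, "wound edges not healed. pt claims pain is gone.")$is_positive)
})

test_that("annotated example notes are recovered exactly", {
  m <- compile_matcher(default_lexicon())
  ex <- judgment_examples()
  for (i in seq_len(nrow(ex))) {
    r <- match_note(m, ex$text[i])
    expect_true(r$is_positive)
    expect_setequal(r$distinct_terms, ex$canonical_terms[[i]])
    expect_equal(r$n_judgment_words, ex$n_occurrences[i])
  }
})

test_that("matching is deterministic and monotone in the lexicon", {
  m <- compile_matcher(default_lexicon())
  ex <- judgment_examples()
  r1 <- lapply(ex$text, function(t) match_note(m, t))
  r2 <- lapply(ex$text, function(t) match_note(m, t))
  expect_identical(r1, r2)

  # adding a surface form never decreases n_judgment_words
  lex_small <- judgment_lexicon(seeds = c("claims", "states"))
  lex_big <- judgment_lexicon(seeds = c("claims", "states"),
                              variants = list(claims = "claimed",
                                              admits = character()))
  m_small <- compile_matcher(lex_small)
  m_big <- compile_matcher(lex_big)
  texts <- c(ex$text, small_corpus()$notes$text[1:50])
  for (t in texts) {
    expect_gte(match_note(m_big, t)$n_judgment_words,
               match_note(m_small, t)$n_judgment_words)
  }
})

test_that("on cue-free notes the matcher equals a brute-force boundary scan", {
  lex <- default_lexicon()
  m <- compile_matcher(lex)
  surfaces <- lexicon_surfaces(lex)
  uni <- surfaces$surface[!grepl(" ", surfaces$surface)]
  set.seed(42)
  words <- c("fever", "pain", "walker", "dressing", "claims", "adamant",
             "states", "insisted", "log", "diet", "believes", "stairs")
  for (i in 1:40) {
    txt <- paste(sample(words, 12, replace = TRUE), collapse = " ")
    expect_equal(match_note(m, txt)$n_judgment_words,
                 oracle_boundary_scan(uni, txt))
  }
})

test_that("label_corpus summarizes notes and patients, rejects duplicate ids", {
  cp <- small_corpus()
  lab <- small_labels()
  expect_equal(nrow(lab$results), nrow(cp$notes))
  expect_equal(lab$summary$n_notes, nrow(cp$notes))
  by_pat <- tapply(lab$results$is_positive, lab$results$patient_id, any)
  expect_equal(lab$summary$n_patients_positive, sum(by_pat))

  dup <- cp$notes[c(1, 1, 2), ]
  expect_error(label_corpus(compile_matcher(default_lexicon()), dup), "duplicate")
})

test_that("matcher recovers generator ground truth with high sensitivity/specificity", {
  cp <- small_corpus()
  lab <- small_labels()
  truth <- cp$truth$is_positive[match(lab$results$note_id, cp$truth$note_id)]
  pred <- lab$results$is_positive
  sensitivity <- sum(pred & truth) / sum(truth)
  specificity <- sum(!pred & !truth) / sum(!truth)
  expect_gte(sensitivity, 0.95)
  expect_gte(specificity, 0.95)
  # planted provider-attributed confounders contribute no false positives
  has_conf <- vapply(cp$truth$planted_confounders, nrow, 0L) > 0L
  expect_equal(sum(pred[match(cp$truth$note_id[has_conf], lab$results$note_id)]), 0L)
})

test_that("a corpus containing only provider-attributed confounders yields 0 positives", {
  cc <- corpus_config(200, judgment_rate_by_race = c(White = 0, Black = 0,
                                                     Hispanic = 0, Asian = 0),
                      confounder_rate = 1, seed = 17L)
  cp <- generate_corpus(cc)
  lab <- label_corpus(compile_matcher(default_lexicon()), cp$notes)
  expect_equal(lab$summary$n_positive, 0L)
  expect_gt(sum(lab$results$n_excluded), 0L)
})
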