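test_that("contingency arithmetic reproduces the reference cohort table", {
  ct <- contingency_from_counts(table2_counts(), reference = "White")
  expect_equal(round(ct$pct_positive, 1), c(9.5, 7.8, 10.8, 10.7))
  expect_equal(round(ct$relative_change_vs_ref, 0), c(0, -18, 14, 13))
  expect_error(contingency_from_counts(table2_counts(), reference = "Other"),
               "absent")
})

test_that("degenerate contingency cases behave", {
  one <- contingency_from_counts(
    tibble::tibble(group = "A", n_notes = 10L, n_positive = 10L), reference = "A")
  expect_equal(one$pct_positive, 100)
  expect_equal(one$relative_change_vs_ref, 0)

  eq <- contingency_from_counts(
    tibble::tibble(group = c("A", "B"), n_notes = c(100L, 50L),
                   n_positive = c(10L, 5L)), reference = "A")
  expect_equal(eq$relative_change_vs_ref, c(0, 0))
})

test_that("chi-square matches the Pearson formula oracle", {
  ct <- contingency_from_counts(table2_counts(), reference = "White")
  res <- chi_square_test(ct)
  tab <- cbind(ct$n_positive, ct$n_notes - ct$n_positive)
  expect_equal(res$statistic, oracle_pearson(tab), tolerance = 1e-6)
  expect_equal(res$df, 3)
  expect_lt(res$p_value, 0.001)

  same <- contingency_from_counts(
    tibble::tibble(group = c("A", "B"), n_notes = c(200L, 100L),
                   n_positive = c(20L, 10L)), reference = "A")
  expect_equal(chi_square_test(same)$statistic, 0, tolerance = 1e-12)
})

test_that("logistic fit matches closed-form 2x2 odds ratio and Newton oracle", {
  # saturated single-predictor model: OR = ad/bc
  a <- 30; b <- 70; c <- 10; d <- 90
  df <- data.frame(
    is_positive = rep(c(1, 0, 1, 0), c(a, b, c, d)),
    grp = rep(c("x", "x", "ref", "ref"), c(a, b, c, d))
  )
  df$grp <- stats::relevel(factor(df$grp), "ref")
  fit <- fit_logistic(df, is_positive ~ grp, reference_race = "White")
  or <- fit$coefficients$or[fit$coefficients$term == "grpx"]
  expect_equal(or, (a * d) / (b * c), tolerance = 1e-6)

  X <- stats::model.matrix(~grp, df)
  beta <- oracle_logistic(df$is_positive, X)
  expect_equal(fit$coefficients$estimate, unname(beta), tolerance = 1e-6)
})

test_that("balanced groups with identical rates give a null group coefficient", {
  df <- data.frame(
    is_positive = rep(c(1, 0, 1, 0), c(25, 75, 25, 75)),
    grp = rep(c("a", "a", "b", "b"), c(25, 75, 25, 75))
  )
  fit <- fit_logistic(df, is_positive ~ grp)
  expect_equal(fit$coefficients$estimate[2], 0, tolerance = 1e-8)
})

test_that("separation and rank deficiency raise explicit errors", {
  df <- data.frame(is_positive = c(rep(1, 20), rep(0, 20)),
                   grp = rep(c("a", "b"), each = 20))
  expect_error(fit_logistic(df, is_positive ~ grp), "separation")

  df2 <- data.frame(is_positive = rbinom(40, 1, 0.5),
                    x1 = rep(c(0, 1), 20))
  df2$x2 <- df2$x1
  expect_error(fit_logistic(df2, is_positive ~ x1 + x2), "aliased")
})

test_that("race odds-ratio CIs cover the planted marginal odds ratios", {
  # planted rates with no clinician effect: OR recovery across replicates
  rates <- c(White = 0.095, Black = 0.107, Hispanic = 0.108, Asian = 0.078)
  target_or <- (rates / (1 - rates)) / (rates[["White"]] / (1 - rates[["White"]]))
  cover <- matrix(NA, 20, 3, dimnames = list(NULL, c("Black", "Hispanic", "Asian")))
  for (r in 1:20) {
    cp <- generate_corpus(corpus_config(1500, clinician_re_sd = 0, seed = 9000L + r))
    df <- dplyr::inner_join(cp$truth[, c("note_id", "is_positive")],
                            cp$notes[, c("note_id", "patient_id")], by = "note_id")
    df <- dplyr::inner_join(df, cp$patients, by = "patient_id")
    fit <- fit_logistic(df)
    for (g in colnames(cover)) {
      row <- fit$coefficients[fit$coefficients$term == paste0("race_ethnicity", g), ]
      cover[r, g] <- row$or_lo <= target_or[[g]] && target_or[[g]] <= row$or_hi
    }
  }
  expect_gte(mean(cover), 0.90)
})

test_that("mixed fit degenerates to the fixed fit when no clinician effect exists", {
  # large per-clinician note counts so the boundary SD estimate is informative
  cp <- generate_corpus(corpus_config(8000, clinician_re_sd = 0,
                                      n_clinicians = 50, seed = 55L))
  df <- model_frame(cp, label_corpus(compile_matcher(default_lexicon()), cp$notes))
  fx <- fit_logistic(df)
  mx <- fit_mixed_logistic(df)
  expect_lt(mx$re_sd, 0.05)
  expect_lt(abs(mx$log_likelihood - fx$log_likelihood), 0.5)
  # exact zero-SD likelihood identity
  beta <- fx$coefficients$estimate
  ll0 <- mixed_logit_loglik(df, beta, 0)
  expect_equal(ll0, fx$log_likelihood, tolerance = 1e-6)
})

test_that("mixed fit recovers a planted clinician SD and matches the glmer oracle", {
  skip_if_not_installed("lme4")
  cp <- generate_corpus(corpus_config(2500, clinician_re_sd = 1.0,
                                      n_clinicians = 200, seed = 66L))
  df <- dplyr::inner_join(cp$truth[, c("note_id", "is_positive")],
                          cp$notes, by = "note_id")
  df <- dplyr::inner_join(df, cp$patients, by = "patient_id")
  mx <- fit_mixed_logistic(df, quadrature_order = 15)
  expect_gte(mx$re_sd, 0.8)
  expect_lte(mx$re_sd, 1.2)

  df_o <- df
  df_o$race_ethnicity <- stats::relevel(factor(df_o$race_ethnicity), "White")
  gm <- lme4::glmer(is_positive ~ race_ethnicity + gender + (1 | clinician_id),
                    data = df_o, family = stats::binomial(), nAGQ = 15)
  expect_equal(mx$log_likelihood, as.numeric(stats::logLik(gm)), tolerance = 1e-4)
  expect_equal(mx$re_sd, sqrt(unlist(lme4::VarCorr(gm))[[1]]), tolerance = 1e-3)
  expect_equal(mx$coefficients$estimate, unname(lme4::fixef(gm)), tolerance = 1e-3)
})

test_that("the quadrature is order-stable and the preconditions are enforced", {
  cp <- generate_corpus(corpus_config(300, clinician_re_sd = 0.8,
                                      n_clinicians = 25, seed = 77L))
  df <- dplyr::inner_join(cp$truth[, c("note_id", "is_positive")],
                          cp$notes, by = "note_id")
  df <- dplyr::inner_join(df, cp$patients, by = "patient_id")
  mx <- fit_mixed_logistic(df, quadrature_order = 15)
  ll15 <- mixed_logit_loglik(df, mx$coefficients$estimate, mx$re_sd,
                             quadrature_order = 15)
  ll41 <- mixed_logit_loglik(df, mx$coefficients$estimate, mx$re_sd,
                             quadrature_order = 41)
  expect_lt(abs(ll41 - ll15), 1e-4)
  expect_error(fit_mixed_logistic(df, quadrature_order = 8), "odd")
  expect_error(fit_mixed_logistic(df[df$clinician_id == df$clinician_id[1], ],
                                  quadrature_order = 15), "2 clusters")
})

test_that("model comparison arithmetic and boundary-mixture p-value", {
  fake_fixed <- structure(list(log_likelihood = -120), class = "logit_fit")
  fake_mixed <- structure(list(log_likelihood = -100), class = "mixed_logit_fit")
  cmp <- compare_models(fake_fixed, fake_mixed)
  expect_equal(cmp$lrt_statistic, 40)
  expect_equal(cmp$relative_ll_change, 20)
  expect_equal(cmp$p_value, 0.5 * stats::pchisq(40, 1, lower.tail = FALSE))

  same <- compare_models(structure(list(log_likelihood = -50), class = "logit_fit"),
                         structure(list(log_likelihood = -50), class = "mixed_logit_fit"))
  expect_equal(same$lrt_statistic, 0)
  expect_equal(same$relative_ll_change, 0)
  expect_equal(same$p_value, 1)

  expect_error(compare_models(structure(list(log_likelihood = -40), class = "logit_fit"),
                              structure(list(log_likelihood = -50), class = "mixed_logit_fit")),
               "optimizer failure")
})

test_that("visit-time linear model: exact two-point slope and noiseless recovery", {
  # zero-residual fixtures: lm warns about the perfect fit, by construction
  two <- data.frame(visit_minutes = c(70, 49), n_judgment_words = c(0, 1))
  fit <- suppressWarnings(fit_linear_visit_time(two, visit_minutes ~ n_judgment_words))
  expect_equal(fit$decrement_per_word, 21, tolerance = 1e-10)

  set.seed(1)
  w <- rpois(200, 0.6)
  noiseless <- data.frame(visit_minutes = 70 - 21 * w, n_judgment_words = w)
  fit2 <- suppressWarnings(fit_linear_visit_time(noiseless, visit_minutes ~ n_judgment_words))
  expect_equal(fit2$decrement_per_word, 21, tolerance = 1e-8)

  const <- data.frame(visit_minutes = rnorm(10, 70), n_judgment_words = rep(1, 10))
  expect_error(fit_linear_visit_time(const, visit_minutes ~ n_judgment_words),
               "aliased")
})

test_that("group mean difference handles fixtures and empty classes", {
  df <- data.frame(visit_minutes = c(46, 46, 70, 70),
                   is_positive = c(TRUE, TRUE, FALSE, FALSE))
  gm <- group_mean_difference(df)
  expect_equal(gm$mean_positive, 46)
  expect_equal(gm$mean_negative, 70)
  expect_equal(gm$difference, 24)
  expect_error(group_mean_difference(df[df$is_positive, ]), "required")
})
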