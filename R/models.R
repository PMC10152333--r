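# Regression models for the disparity analysis: fixed-effects logistic
# (glm/IRLS), clinician-random-intercept logistic (adaptive Gauss-Hermite
# quadrature, implemented here), their likelihood comparison, and the
# visit-time linear model.

set_reference_levels <- function(data, reference_race = "White") {
  data <- as.data.frame(data)
  if ("race_ethnicity" %in% names(data)) {
    lev <- unique(data$race_ethnicity)
    if (!reference_race %in% lev) {
      stop("reference race '", reference_race, "' absent from the data", call. = FALSE)
    }
    data$race_ethnicity <- stats::relevel(factor(data$race_ethnicity), ref = reference_race)
  }
  if ("gender" %in% names(data)) {
    tab <- table(data$gender)
    data$gender <- stats::relevel(factor(data$gender),
                                  ref = names(tab)[which.max(tab)])
  }
  data
}

#' Fixed-effects logistic regression of judgment-language presence
#'
#' Maximum-likelihood logistic fit via iteratively reweighted least squares,
#' with odds ratios and 95% Wald confidence intervals. Reference categories
#' are the supplied race (default White) and the modal gender level.
#'
#' @param data data frame with the binary outcome and covariates.
#' @param formula model formula (default
#'   `is_positive ~ race_ethnicity + gender`).
#' @param reference_race reference race level.
#' @return object of class `logit_fit`: `coefficients` tibble (`term`,
#'   `estimate`, `se`, `or`, `or_lo`, `or_hi`, `p_value`), `log_likelihood`,
#'   `converged`, `iterations`, `n`. Errors on separation or a rank-deficient
#'   design.
#' @export
fit_logistic <- function(data, formula = is_positive ~ race_ethnicity + gender,
                         reference_race = "White") {
  data <- set_reference_levels(data, reference_race)
  sep_warn <- FALSE
  fit <- withCallingHandlers(
    stats::glm(formula, family = stats::binomial(), data = data,
               control = stats::glm.control(epsilon = 1e-10, maxit = 100)),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w))) {
        sep_warn <<- TRUE
        invokeRestart("muffleWarning")
      }
    }
  )
  cf <- stats::coef(fit)
  if (anyNA(cf)) {
    stop("rank-deficient design; aliased column(s): ",
         paste(names(cf)[is.na(cf)], collapse = ", "), call. = FALSE)
  }
  if (sep_warn || any(abs(cf) > 15)) {
    stop("separation detected: coefficient estimates diverge", call. = FALSE)
  }
  sm <- summary(fit)$coefficients
  z <- stats::qnorm(0.975)
  coefficients <- tibble::tibble(
    term = rownames(sm),
    estimate = unname(sm[, 1L]),
    se = unname(sm[, 2L]),
    or = exp(unname(sm[, 1L])),
    or_lo = exp(unname(sm[, 1L] - z * sm[, 2L])),
    or_hi = exp(unname(sm[, 1L] + z * sm[, 2L])),
    p_value = unname(sm[, 4L])
  )
  structure(
    list(coefficients = coefficients,
         log_likelihood = as.numeric(stats::logLik(fit)),
         converged = fit$converged,
         iterations = fit$iter,
         n = stats::nobs(fit),
         formula = formula),
    class = "logit_fit"
  )
}

# ---- mixed logistic: adaptive Gauss-Hermite quadrature -----------------------

# Aggregate Bernoulli rows to binomial counts per unique (cluster, design row).
aggregate_binomial <- function(y, X, cluster) {
  key <- paste(cluster, apply(X, 1L, paste, collapse = "\r"), sep = "\r")
  grp <- match(key, unique(key))
  s <- rowsum(as.numeric(y), grp)[, 1L]
  m <- rowsum(rep(1, length(y)), grp)[, 1L]
  first <- !duplicated(grp)
  list(s = s, m = m, X = X[first, , drop = FALSE],
       cluster = as.integer(factor(cluster[first])))
}

# Per-cluster random-effect modes and curvatures at (beta, sd), by Newton.
cluster_modes <- function(eta, s, m, cl, J, sd) {
  u <- numeric(J)
  for (it in seq_len(60L)) {
    p <- stats::plogis(eta + u[cl])
    g <- rowsum(s - m * p, cl)[, 1L] - u / sd^2
    h <- -rowsum(m * p * (1 - p), cl)[, 1L] - 1 / sd^2
    step <- g / h
    step <- pmin(pmax(step, -4), 4)
    u <- u - step
    if (max(abs(g)) < 1e-10) break
  }
  p <- stats::plogis(eta + u[cl])
  h <- -rowsum(m * p * (1 - p), cl)[, 1L] - 1 / sd^2
  list(mode = u, tau = 1 / sqrt(-h))
}

# Marginal log-likelihood by adaptive Gauss-Hermite quadrature.
agq_loglik <- function(beta, sd, agg, gh) {
  eta <- as.vector(agg$X %*% beta)
  cl <- agg$cluster
  J <- max(cl)
  if (sd < 1e-8) {
    lp1 <- stats::plogis(eta, log.p = TRUE)
    lp0 <- stats::plogis(-eta, log.p = TRUE)
    return(sum(agg$s * lp1 + (agg$m - agg$s) * lp0))
  }
  md <- cluster_modes(eta, agg$s, agg$m, cl, J, sd)
  K <- length(gh$x)
  a <- matrix(0, J, K)
  for (k in seq_len(K)) {
    u_k <- md$mode + sqrt(2) * md$tau * gh$x[k]
    et <- eta + u_k[cl]
    ll_rows <- agg$s * stats::plogis(et, log.p = TRUE) +
      (agg$m - agg$s) * stats::plogis(-et, log.p = TRUE)
    h <- rowsum(ll_rows, cl)[, 1L] + stats::dnorm(u_k, 0, sd, log = TRUE)
    a[, k] <- log(gh$w[k]) + gh$x[k]^2 + h
  }
  sum(log(sqrt(2) * md$tau) + row_logsumexp(a))
}

#' Random-intercept logistic regression by adaptive Gauss-Hermite quadrature
#'
#' Fits a logistic regression with a Normal(0, sd^2) random intercept per
#' cluster (clinician). The marginal likelihood is integrated per cluster by
#' adaptive Gauss-Hermite quadrature (nodes centered at each cluster's
#' conditional mode and scaled by its curvature) and maximized over the fixed
#' effects and log-SD with L-BFGS-B. Deterministic given the data.
#'
#' @param data data frame with outcome, covariates and a cluster id column.
#' @param formula fixed-effects formula (default
#'   `is_positive ~ race_ethnicity + gender`).
#' @param cluster name of the cluster id column (default `"clinician_id"`).
#' @param quadrature_order odd integer >= 7 (default 15).
#' @param reference_race reference race level.
#' @return object of class `mixed_logit_fit`: `coefficients` tibble, `re_sd`,
#'   `log_likelihood`, `quadrature_order`, `converged`, `iterations`, `n`,
#'   `n_clusters`. An SD estimate pinned at the zero boundary is reported,
#'   not an error; non-convergence of the optimizer is an error.
#' @export
fit_mixed_logistic <- function(data, formula = is_positive ~ race_ethnicity + gender,
                               cluster = "clinician_id", quadrature_order = 15L,
                               reference_race = "White") {
  if (quadrature_order < 7L || quadrature_order %% 2L == 0L) {
    stop("`quadrature_order` must be an odd integer >= 7", call. = FALSE)
  }
  data <- set_reference_levels(data, reference_race)
  if (!cluster %in% names(data)) stop("cluster column '", cluster, "' not found", call. = FALSE)
  if (length(unique(data[[cluster]])) < 2L) {
    stop("need at least 2 clusters to estimate a random intercept", call. = FALSE)
  }
  mf <- stats::model.frame(formula, data = data)
  y <- as.numeric(stats::model.response(mf))
  X <- stats::model.matrix(formula, mf)
  agg <- aggregate_binomial(y, X, data[[cluster]])
  gh <- pracma::gaussHermite(as.integer(quadrature_order))

  start_fit <- stats::glm.fit(agg$X, agg$s / agg$m, weights = agg$m,
                              family = stats::binomial())
  p <- ncol(X)
  theta0 <- c(unname(stats::coef(start_fit)), log(0.5))
  negll <- function(theta) {
    -agq_loglik(theta[seq_len(p)], exp(theta[p + 1L]), agg, gh)
  }
  opt <- stats::optim(theta0, negll, method = "L-BFGS-B",
                      lower = c(rep(-Inf, p), -8), upper = c(rep(Inf, p), 3),
                      control = list(maxit = 500, factr = 1e6))
  if (opt$convergence != 0) {
    stop("mixed-model optimizer failed to converge: code ", opt$convergence,
         " (", opt$message, ")", call. = FALSE)
  }
  est <- opt$par
  re_sd <- exp(est[p + 1L])
  boundary <- est[p + 1L] <= -7.5

  se <- rep(NA_real_, p)
  hess <- try(stats::optimHess(est, negll), silent = TRUE)
  if (!inherits(hess, "try-error")) {
    vc <- try(solve(hess), silent = TRUE)
    if (!inherits(vc, "try-error") && all(diag(vc)[seq_len(p)] > 0)) {
      se <- sqrt(diag(vc)[seq_len(p)])
    }
  }

  structure(
    list(coefficients = tibble::tibble(term = colnames(X),
                                       estimate = est[seq_len(p)], se = se),
         re_sd = if (boundary) 0 else re_sd,
         re_sd_boundary = boundary,
         log_likelihood = -opt$value,
         quadrature_order = as.integer(quadrature_order),
         converged = TRUE,
         iterations = unname(opt$counts[1L]),
         n = length(y),
         n_clusters = max(agg$cluster),
         formula = formula, cluster = cluster),
    class = "mixed_logit_fit"
  )
}

#' Evaluate the mixed-logit marginal log-likelihood at given parameters
#'
#' Exposes the adaptive-quadrature likelihood so quadrature-order stability
#' can be checked directly.
#'
#' @inheritParams fit_mixed_logistic
#' @param beta fixed-effect vector (in `model.matrix` column order).
#' @param re_sd random-intercept SD (>= 0).
#' @return the marginal log-likelihood (a scalar).
#' @export
mixed_logit_loglik <- function(data, beta, re_sd,
                               formula = is_positive ~ race_ethnicity + gender,
                               cluster = "clinician_id", quadrature_order = 15L,
                               reference_race = "White") {
  data <- set_reference_levels(data, reference_race)
  mf <- stats::model.frame(formula, data = data)
  y <- as.numeric(stats::model.response(mf))
  X <- stats::model.matrix(formula, mf)
  agg <- aggregate_binomial(y, X, data[[cluster]])
  gh <- pracma::gaussHermite(as.integer(quadrature_order))
  agq_loglik(beta, re_sd, agg, gh)
}

#' Compare fixed and mixed logistic fits by likelihood ratio
#'
#' The random intercept nests the fixed model, so the LRT statistic
#' `2 * (ll_mixed - ll_fixed)` is nonnegative up to numerical tolerance; its
#' null distribution is the boundary 50:50 mixture of chi-square(0) and
#' chi-square(1).
#'
#' @param fixed a `logit_fit`.
#' @param mixed a `mixed_logit_fit` on the same data with nested fixed
#'   effects.
#' @return list with `ll_fixed`, `ll_mixed`, `lrt_statistic`, `p_value` and
#'   `relative_ll_change` (= 100 * (ll_fixed - ll_mixed) / |ll_mixed|).
#' @export
compare_models <- function(fixed, mixed) {
  ll_f <- fixed$log_likelihood
  ll_m <- mixed$log_likelihood
  lrt <- 2 * (ll_m - ll_f)
  if (lrt < -1e-6) {
    stop("mixed log-likelihood below fixed log-likelihood: optimizer failure",
         call. = FALSE)
  }
  lrt <- max(lrt, 0)
  p <- if (lrt <= 0) 1 else 0.5 * stats::pchisq(lrt, df = 1, lower.tail = FALSE)
  # relative size of the log-likelihood drop when the random effect is
  # removed: (-120 vs -100) -> 20%
  list(ll_fixed = ll_f, ll_mixed = ll_m, lrt_statistic = lrt, p_value = p,
       relative_ll_change = 100 * (ll_m - ll_f) / abs(ll_m))
}

#' Linear model of visit minutes on judgment-word count
#'
#' Ordinary least squares of visit minutes on the number of judgment-word
#' occurrences per note, adjusted for race/ethnicity and gender. The reported
#' decrement is minus the word-count coefficient (minutes lost per judgment
#' word).
#'
#' @param data data frame with `visit_minutes`, `n_judgment_words`,
#'   `race_ethnicity`, `gender` (as given by joining notes, match results and
#'   patients).
#' @param formula model formula.
#' @param reference_race reference race level.
#' @return object of class `linear_fit`: `coefficients` tibble (`term`,
#'   `estimate`, `se`, `ci_lo`, `ci_hi`, `p_value`), `decrement_per_word`,
#'   `residual_sd`, `n`.
#' @export
fit_linear_visit_time <- function(data,
                                  formula = visit_minutes ~ n_judgment_words +
                                    race_ethnicity + gender,
                                  reference_race = "White") {
  data <- set_reference_levels(data, reference_race)
  if ("n_judgment_words" %in% all.vars(formula) &&
      length(unique(data$n_judgment_words)) < 2L) {
    stop("all judgment-word counts are identical; the word-count effect is aliased",
         call. = FALSE)
  }
  fit <- stats::lm(formula, data = data)
  cf <- stats::coef(fit)
  if (anyNA(cf)) {
    stop("rank-deficient design; aliased column(s): ",
         paste(names(cf)[is.na(cf)], collapse = ", "), call. = FALSE)
  }
  sm <- summary(fit)$coefficients
  ci <- stats::confint(fit, level = 0.95)
  coefficients <- tibble::tibble(
    term = rownames(sm), estimate = unname(sm[, 1L]), se = unname(sm[, 2L]),
    ci_lo = unname(ci[, 1L]), ci_hi = unname(ci[, 2L]), p_value = unname(sm[, 4L])
  )
  wc <- coefficients[coefficients$term == "n_judgment_words", , drop = FALSE]
  structure(
    list(coefficients = coefficients,
         decrement_per_word = if (nrow(wc)) unname(-wc$estimate) else NA_real_,
         decrement_ci = if (nrow(wc)) unname(c(-wc$ci_hi, -wc$ci_lo)) else c(NA_real_, NA_real_),
         residual_sd = summary(fit)$sigma,
         n = stats::nobs(fit)),
    class = "linear_fit"
  )
}

#' Mean visit length by judgment-language status
#'
#' @param data data frame with `visit_minutes` and `is_positive`; both classes
#'   must be nonempty.
#' @return list with `mean_positive`, `mean_negative` and `difference`
#'   (= mean_negative - mean_positive, minutes).
#' @export
group_mean_difference <- function(data) {
  pos <- data$visit_minutes[data$is_positive]
  neg <- data$visit_minutes[!data$is_positive]
  if (length(pos) == 0L || length(neg) == 0L) {
    stop("both judgment-positive and judgment-negative notes are required",
         call. = FALSE)
  }
  list(mean_positive = mean(pos), mean_negative = mean(neg),
       difference = mean(neg) - mean(pos))
}
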