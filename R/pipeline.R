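#' Configure a pipeline run
#'
#' Exactly one corpus source (a [corpus_config()] to generate, or a path to a
#' corpus written by [write_corpus()]) and one lexicon source (a
#' `judgment_lexicon`, or a path to a lexicon JSON) must be given.
#'
#' @param corpus_config a [corpus_config()] (generate a synthetic corpus).
#' @param corpus_path directory of an existing corpus.
#' @param lexicon a `judgment_lexicon` (default [default_lexicon()]).
#' @param lexicon_path path to a lexicon JSON from [save_lexicon()].
#' @param out_dir output directory for stage artifacts.
#' @param seed global seed, fanned out to per-stage child seeds via
#'   [stage_seed()].
#' @param attribution_window matcher window `W` in tokens.
#' @param reference_group reference race/ethnicity for contingency and models.
#' @param quadrature_order quadrature order for the mixed model.
#' @param fit_mixed whether to fit the clinician-random-intercept model.
#' @param log_level "quiet" or "info".
#' @return object of class `run_config`.
#' @export
run_config <- function(corpus_config = NULL, corpus_path = NULL,
                       lexicon = NULL, lexicon_path = NULL,
                       out_dir = tempfile("judgmentlang-run-"),
                       seed = 1L,
                       attribution_window = 5L,
                       reference_group = "White",
                       quadrature_order = 15L,
                       fit_mixed = TRUE,
                       log_level = c("info", "quiet")) {
  if (is.null(corpus_config) == is.null(corpus_path)) {
    stop("exactly one of `corpus_config` or `corpus_path` must be given", call. = FALSE)
  }
  if (!is.null(lexicon) && !is.null(lexicon_path)) {
    stop("give at most one of `lexicon` or `lexicon_path`", call. = FALSE)
  }
  structure(
    list(corpus_config = corpus_config, corpus_path = corpus_path,
         lexicon = lexicon %||% if (is.null(lexicon_path)) default_lexicon() else NULL,
         lexicon_path = lexicon_path,
         out_dir = out_dir, seed = as.integer(seed),
         attribution_window = as.integer(attribution_window),
         reference_group = reference_group,
         quadrature_order = as.integer(quadrature_order),
         fit_mixed = isTRUE(fit_mixed),
         log_level = match.arg(log_level)),
    class = "run_config"
  )
}

pipeline_log <- function(config, ...) {
  if (identical(config$log_level, "info")) message("[judgmentlang] ", ...)
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE)
  })
}

#' Run the full analysis pipeline
#'
#' Orchestrates corpus acquisition, lexicon loading, note labeling and the
#' disparity statistics as one reproducible run. All stage artifacts are
#' written under `config$out_dir`, together with a manifest (config hash,
#' seed, stage seeds, package version) sufficient to re-run the pipeline
#' reproducibly. A stage failure aborts with the stage name; artifacts of
#' completed stages are preserved on disk.
#'
#' @param config a [run_config()].
#' @return a `run_report` list: `contingency`, `chi_square`, `fit_fixed`,
#'   `fit_mixed` (or NULL), `model_comparison` (or NULL), `fit_visit_time`,
#'   `visit_means`, `label_summary`, `report`, `manifest`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)

  corpus <- run_stage("corpus", {
    if (!is.null(config$corpus_config)) {
      cc <- config$corpus_config
      pipeline_log(config, "generating synthetic corpus (", cc$n_patients, " patients)")
      cp <- generate_corpus(cc)
      write_corpus(cp, file.path(config$out_dir, "corpus"))
      cp
    } else {
      pipeline_log(config, "loading corpus from ", config$corpus_path)
      read_corpus(config$corpus_path)
    }
  })

  lexicon <- run_stage("lexicon", {
    lx <- if (!is.null(config$lexicon_path)) load_lexicon(config$lexicon_path) else config$lexicon
    save_lexicon(lx, file.path(config$out_dir, "lexicon.json"))
    lx
  })

  labeled <- run_stage("match", {
    matcher <- compile_matcher(lexicon, attribution_window = config$attribution_window)
    lab <- label_corpus(matcher, corpus$notes)
    pipeline_log(config, "labeled ", lab$summary$n_notes, " notes; ",
                 lab$summary$n_positive, " positive")
    utils::write.csv(
      data.frame(note_id = lab$results$note_id,
                 is_positive = lab$results$is_positive,
                 n_judgment_words = lab$results$n_judgment_words),
      file.path(config$out_dir, "labels.csv"), row.names = FALSE)
    lab
  })

  stats_out <- run_stage("stats", {
    ct <- build_contingency(labeled$results, corpus$patients,
                            reference = config$reference_group)
    chi <- chi_square_test(ct)
    model_df <- dplyr::inner_join(labeled$results, corpus$patients, by = "patient_id")
    model_df <- dplyr::inner_join(
      model_df,
      corpus$notes[, c("note_id", "clinician_id", "visit_minutes")],
      by = "note_id")
    fixed <- fit_logistic(model_df, reference_race = config$reference_group)
    mixed <- NULL
    cmp <- NULL
    if (config$fit_mixed) {
      mixed <- fit_mixed_logistic(model_df,
                                  quadrature_order = config$quadrature_order,
                                  reference_race = config$reference_group)
      cmp <- compare_models(fixed, mixed)
    }
    lin <- fit_linear_visit_time(model_df, reference_race = config$reference_group)
    means <- group_mean_difference(model_df)
    rep_tbl <- report_table(ct, fixed, mixed)
    write_report(rep_tbl, config$out_dir)
    fits_json <- list(
      fixed = list(coefficients = fixed$coefficients,
                   log_likelihood = fixed$log_likelihood),
      mixed = if (!is.null(mixed)) list(coefficients = mixed$coefficients,
                                        re_sd = mixed$re_sd,
                                        log_likelihood = mixed$log_likelihood),
      comparison = cmp,
      visit_time = list(coefficients = lin$coefficients,
                        decrement_per_word = lin$decrement_per_word),
      visit_means = means
    )
    writeLines(as.character(jsonlite::toJSON(fits_json, auto_unbox = TRUE,
                                             digits = NA, null = "null")),
               file.path(config$out_dir, "fits.json"))
    list(contingency = ct, chi = chi, fixed = fixed, mixed = mixed, cmp = cmp,
         lin = lin, means = means, report = rep_tbl)
  })

  manifest <- list(
    package_version = as.character(utils::packageVersion("judgmentlang")),
    seed = config$seed,
    stage_seeds = vapply(0:3, function(k) stage_seed(config$seed, k), 0L),
    config_hash = rlang::hash(config[setdiff(names(config), "out_dir")]),
    n_notes = nrow(corpus$notes),
    n_patients = nrow(corpus$patients),
    n_positive = labeled$summary$n_positive
  )
  writeLines(as.character(jsonlite::toJSON(manifest, auto_unbox = TRUE, digits = NA)),
             file.path(config$out_dir, "manifest.json"))

  structure(
    list(contingency = stats_out$contingency, chi_square = stats_out$chi,
         fit_fixed = stats_out$fixed, fit_mixed = stats_out$mixed,
         model_comparison = stats_out$cmp, fit_visit_time = stats_out$lin,
         visit_means = stats_out$means, label_summary = labeled$summary,
         report = stats_out$report, manifest = manifest),
    class = "run_report"
  )
}
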