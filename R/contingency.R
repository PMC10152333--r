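#' Build a per-group contingency table from printed or computed counts
#'
#' @param counts data frame with columns `group`, `n_notes`, `n_positive` and
#'   optionally `n_patients`.
#' @param reference reference group for relative change (default "White").
#' @return tibble of class `group_contingency` with `pct_positive`
#'   (= 100 * n_positive / n_notes) and `relative_change_vs_ref`
#'   (= 100 * (p_g - p_ref) / p_ref; 0 for the reference). Pooled totals are
#'   attached as the `totals` attribute.
#' @export
contingency_from_counts <- function(counts, reference = "White") {
  counts <- tibble::as_tibble(counts)
  stopifnot(all(c("group", "n_notes", "n_positive") %in% names(counts)))
  if (!reference %in% counts$group) {
    stop("reference group '", reference, "' absent from the table", call. = FALSE)
  }
  if (any(counts$n_positive < 0 | counts$n_positive > counts$n_notes)) {
    stop("n_positive must lie in [0, n_notes] for every group", call. = FALSE)
  }
  p <- 100 * counts$n_positive / counts$n_notes
  p_ref <- p[counts$group == reference]
  out <- counts
  out$pct_positive <- p
  out$relative_change_vs_ref <- 100 * (p - p_ref) / p_ref
  out$relative_change_vs_ref[counts$group == reference] <- 0
  attr(out, "reference") <- reference
  attr(out, "totals") <- list(
    n_notes = sum(counts$n_notes),
    n_positive = sum(counts$n_positive),
    pct_positive = 100 * sum(counts$n_positive) / sum(counts$n_notes),
    n_patients = if ("n_patients" %in% names(counts)) sum(counts$n_patients) else NA_integer_
  )
  class(out) <- c("group_contingency", class(out))
  out
}

#' Build the race/ethnicity contingency table from match results
#'
#' @param results note-level results from [label_corpus()] (`patient_id`,
#'   `is_positive`).
#' @param patients patient table with `patient_id`, `race_ethnicity`.
#' @param reference reference group (default "White").
#' @return a `group_contingency` tibble (one row per race/ethnicity with
#'   patient, note and positive counts, percentage and relative change).
#' @export
build_contingency <- function(results, patients, reference = "White") {
  joined <- dplyr::inner_join(
    tibble::as_tibble(results)[, c("note_id", "patient_id", "is_positive")],
    tibble::as_tibble(patients)[, c("patient_id", "race_ethnicity")],
    by = "patient_id"
  )
  if (nrow(joined) < nrow(tibble::as_tibble(results))) {
    stop("some results reference patients missing from the patient table",
         call. = FALSE)
  }
  counts <- dplyr::summarise(
    dplyr::group_by(joined, group = .data$race_ethnicity),
    n_patients = dplyr::n_distinct(.data$patient_id),
    n_notes = dplyr::n(),
    n_positive = sum(.data$is_positive),
    .groups = "drop"
  )
  contingency_from_counts(counts, reference = reference)
}

#' Pearson chi-square test on a group contingency table
#'
#' Tests independence of judgment-language presence and group on the
#' groups x (positive, negative) table, without continuity correction;
#' df = number of groups - 1.
#'
#' @param contingency a `group_contingency`.
#' @return list with `statistic`, `df`, `p_value`.
#' @export
chi_square_test <- function(contingency) {
  tab <- cbind(positive = contingency$n_positive,
               negative = contingency$n_notes - contingency$n_positive)
  rownames(tab) <- contingency$group
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (any(expected <= 0)) {
    stop("zero expected cell count; collapse sparse groups before testing",
         call. = FALSE)
  }
  ht <- stats::chisq.test(tab, correct = FALSE)
  list(statistic = unname(ht$statistic), df = unname(ht$parameter),
       p_value = unname(ht$p.value))
}
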