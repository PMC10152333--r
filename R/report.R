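#' Format the disparity report table
#'
#' Rounds the contingency table to report precision (percentages to 1
#' decimal place, relative change to whole percent, odds ratios to 2 decimal
#' places) and attaches odds ratios from the fitted models.
#'
#' @param contingency a `group_contingency`.
#' @param fixed optional `logit_fit`.
#' @param mixed optional `mixed_logit_fit`.
#' @return tibble with one row per group.
#' @export
report_table <- function(contingency, fixed = NULL, mixed = NULL) {
  reference <- attr(contingency, "reference")
  out <- tibble::tibble(
    group = contingency$group,
    n_patients = if ("n_patients" %in% names(contingency)) contingency$n_patients else NA_integer_,
    n_notes = contingency$n_notes,
    n_positive = contingency$n_positive,
    pct_positive = round(contingency$pct_positive, 1),
    relative_change_vs_ref = round(contingency$relative_change_vs_ref, 0)
  )
  or_col <- function(fit, kind) {
    vals <- rep(NA_character_, nrow(out))
    vals[out$group == reference] <- "Reference"
    for (i in seq_len(nrow(out))) {
      g <- out$group[i]
      if (g == reference) next
      row <- fit$coefficients[fit$coefficients$term == paste0("race_ethnicity", g), , drop = FALSE]
      if (nrow(row) == 1L) {
        if (kind == "fixed") {
          vals[i] <- sprintf("%.2f (%.2f-%.2f)", row$or, row$or_lo, row$or_hi)
        } else {
          z <- stats::qnorm(0.975)
          vals[i] <- sprintf("%.2f (%.2f-%.2f)", exp(row$estimate),
                             exp(row$estimate - z * row$se),
                             exp(row$estimate + z * row$se))
        }
      }
    }
    vals
  }
  if (!is.null(fixed)) out$or_fixed <- or_col(fixed, "fixed")
  if (!is.null(mixed)) out$or_mixed <- or_col(mixed, "mixed")
  out
}

#' Write a report table as CSV and Markdown
#'
#' @param report a tibble from [report_table()].
#' @param dir output directory.
#' @return paths of the written files, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  csv <- file.path(dir, "report.csv")
  md <- file.path(dir, "report.md")
  utils::write.csv(report, csv, row.names = FALSE)
  header <- paste0("| ", paste(names(report), collapse = " | "), " |")
  sep <- paste0("|", paste(rep("---", ncol(report)), collapse = "|"), "|")
  rows <- apply(report, 1L, function(r) paste0("| ", paste(r, collapse = " | "), " |"))
  writeLines(c(header, sep, rows), md)
  invisible(c(csv = csv, md = md))
}
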