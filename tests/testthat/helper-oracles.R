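# Independent oracles, kept deliberately separate from the implementation
# paths they check.

# Newton-Raphson logistic MLE on a dense design matrix.
oracle_logistic <- function(y, X, tol = 1e-12, maxit = 100) {
  beta <- rep(0, ncol(X))
  for (i in seq_len(maxit)) {
    eta <- as.vector(X %*% beta)
    p <- 1 / (1 + exp(-eta))
    W <- p * (1 - p)
    score <- t(X) %*% (y - p)
    H <- t(X) %*% (X * W)
    step <- solve(H, score)
    beta <- beta + as.vector(step)
    if (max(abs(score)) < tol) break
  }
  beta
}

# Textbook Pearson chi-square on a counts matrix.
oracle_pearson <- function(tab) {
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  sum((tab - expected)^2 / expected)
}

# Brute-force word-boundary substring scan (single-token surfaces only),
# with no exclusion logic.
oracle_boundary_scan <- function(surfaces, text) {
  toks <- unlist(strsplit(tolower(text), "[^a-z0-9'.]+"))
  toks <- gsub("^\\.+|\\.+$", "", toks)  # strip leading/trailing periods
  toks <- toks[nzchar(toks)]
  sum(toks %in% surfaces)
}

# Small convenience: joined note-level modeling frame from a corpus + labels.
model_frame <- function(corpus, labels) {
  df <- dplyr::inner_join(labels$results, corpus$patients, by = "patient_id")
  dplyr::inner_join(df, corpus$notes[, c("note_id", "clinician_id", "visit_minutes")],
                    by = "note_id")
}
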