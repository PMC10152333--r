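# Corpus serialization: notes and ground truth as JSON-lines, patient and
# clinician tables as CSV. Round-trip identity is contractual and tested.

span_tbl <- function(x) {
  if (is.null(x) || length(x) == 0L || (is.data.frame(x) && nrow(x) == 0L)) {
    return(tibble::tibble(term = character(), start = integer(), end = integer()))
  }
  tibble::tibble(term = as.character(x$term), start = as.integer(x$start),
                 end = as.integer(x$end))
}

write_jsonl <- function(records, path) {
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  lines <- vapply(records, function(r) {
    as.character(jsonlite::toJSON(r, auto_unbox = TRUE, digits = NA, null = "null"))
  }, "")
  writeLines(lines, con, useBytes = FALSE)
}

read_jsonl <- function(path, what) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lapply(seq_along(lines), function(i) {
    tryCatch(jsonlite::fromJSON(lines[[i]], simplifyVector = TRUE),
             error = function(e) {
               stop(sprintf("parse error in %s at line %d: %s", what, i,
                            conditionMessage(e)), call. = FALSE)
             })
  })
}

#' Write a corpus to disk
#'
#' Writes `notes.jsonl` (keys `note_id`, `patient_id`, `clinician_id`,
#' `text`, `visit_minutes`), `truth.jsonl` (keyed by `note_id`),
#' `patients.csv` (header `patient_id,race_ethnicity,gender`) and
#' `clinicians.csv` under `path`.
#'
#' @param corpus a `note_corpus` from [generate_corpus()] (or an equivalent
#'   list with `patients`, `clinicians`, `notes`, `truth`).
#' @param path directory to create/write into.
#' @return `path`, invisibly.
#' @export
write_corpus <- function(corpus, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  notes <- corpus$notes
  write_jsonl(lapply(seq_len(nrow(notes)), function(i) {
    list(note_id = notes$note_id[i], patient_id = notes$patient_id[i],
         clinician_id = notes$clinician_id[i], text = notes$text[i],
         visit_minutes = notes$visit_minutes[i])
  }), file.path(path, "notes.jsonl"))

  truth <- corpus$truth
  write_jsonl(lapply(seq_len(nrow(truth)), function(i) {
    list(note_id = truth$note_id[i], is_positive = truth$is_positive[i],
         planted_terms = span_tbl(truth$planted_terms[[i]]),
         planted_confounders = span_tbl(truth$planted_confounders[[i]]))
  }), file.path(path, "truth.jsonl"))

  utils::write.csv(corpus$patients, file.path(path, "patients.csv"),
                   row.names = FALSE, fileEncoding = "UTF-8")
  cli <- corpus$clinicians
  cli$intercept <- sprintf("%.17g", cli$intercept)  # lossless double round-trip
  utils::write.csv(cli, file.path(path, "clinicians.csv"),
                   row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a corpus written by [write_corpus()]
#'
#' @param path directory containing `notes.jsonl`, `truth.jsonl`,
#'   `patients.csv`, `clinicians.csv` (the last one optional).
#' @return a `note_corpus` list; `read_corpus(write_corpus(x)) == x`
#'   field-for-field.
#' @export
read_corpus <- function(path) {
  notes_rec <- read_jsonl(file.path(path, "notes.jsonl"), "notes.jsonl")
  notes <- tibble::tibble(
    note_id = vapply(notes_rec, function(r) as.character(r$note_id), ""),
    patient_id = vapply(notes_rec, function(r) as.character(r$patient_id), ""),
    clinician_id = vapply(notes_rec, function(r) as.character(r$clinician_id), ""),
    text = vapply(notes_rec, function(r) as.character(r$text), ""),
    visit_minutes = vapply(notes_rec, function(r) as.double(r$visit_minutes), 0)
  )
  truth_rec <- read_jsonl(file.path(path, "truth.jsonl"), "truth.jsonl")
  truth <- tibble::tibble(
    note_id = vapply(truth_rec, function(r) as.character(r$note_id), ""),
    is_positive = vapply(truth_rec, function(r) as.logical(r$is_positive), NA),
    planted_terms = lapply(truth_rec, function(r) span_tbl(r$planted_terms)),
    planted_confounders = lapply(truth_rec, function(r) span_tbl(r$planted_confounders))
  )
  patients <- tibble::as_tibble(utils::read.csv(
    file.path(path, "patients.csv"), colClasses = "character",
    fileEncoding = "UTF-8"))
  cli_path <- file.path(path, "clinicians.csv")
  clinicians <- if (file.exists(cli_path)) {
    cl <- utils::read.csv(cli_path, colClasses = "character",
                          fileEncoding = "UTF-8")
    cl$intercept <- as.numeric(cl$intercept)
    tibble::as_tibble(cl)
  } else {
    tibble::tibble(clinician_id = unique(notes$clinician_id), intercept = NA_real_)
  }
  structure(list(patients = patients, clinicians = clinicians,
                 notes = notes, truth = truth),
            class = "note_corpus")
}
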