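#' Read visit-level claim records
#'
#' Reads a delimited text file of office consultations. The file must carry a
#' header with at least `patient_id`, `physician_id` and `visit_date`
#' (ISO-8601); an optional `satisfaction` column holds the 0-10 post-visit
#' patient score. Rows are never silently dropped: every input row ends up
#' either in the returned tibble or in an explicit rejection.
#'
#' @param path Path to a CSV file.
#' @param config A [study_config()]; controls the study window, what happens to
#'   out-of-window rows (`window_action`) and duplicate handling
#'   (`dedupe_visits`).
#' @return A tibble with columns `patient_id`, `physician_id`, `visit_date`
#'   (Date), `satisfaction` (double, `NA` when absent) and `in_window`
#'   (logical). With `window_action = "drop"` the dropped rows are attached as
#'   attribute `"rejected"`.
#' @export
read_visits <- function(path, config = study_config()) {
  if (!file.exists(path)) abort(paste0("File not found: ", path))
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  required <- c("patient_id", "physician_id", "visit_date")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols) > 0) {
    abort(paste0("Visit file is missing required column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  dates <- as.Date(raw$visit_date, format = "%Y-%m-%d")
  bad <- which(is.na(dates) | is.na(raw$visit_date))
  if (length(bad) > 0) {
    abort(paste0("Unparseable visit_date at data row(s): ",
                 paste(head(bad, 10), collapse = ", "),
                 if (length(bad) > 10) " ..." else ""))
  }
  sat <- if ("satisfaction" %in% names(raw)) {
    suppressWarnings(as.numeric(raw$satisfaction))
  } else {
    rep(NA_real_, nrow(raw))
  }
  if (any(!is.na(sat) & (sat < 0 | sat > 10))) {
    abort("`satisfaction` values must lie in [0, 10].")
  }
  visits <- tibble::tibble(
    patient_id = raw$patient_id,
    physician_id = raw$physician_id,
    visit_date = dates,
    satisfaction = sat,
    in_window = dates >= config$study_start & dates <= config$study_end
  )
  n_out <- sum(!visits$in_window)
  if (n_out > 0 && config$window_action == "error") {
    abort(paste0(n_out, " visit row(s) dated outside the study window [",
                 format(config$study_start), ", ", format(config$study_end), "]; ",
                 "first offending data row: ", which(!visits$in_window)[1]))
  }
  rejected <- visits[0, ]
  if (n_out > 0 && config$window_action == "drop") {
    rejected <- dplyr::filter(visits, !.data$in_window)
    visits <- dplyr::filter(visits, .data$in_window)
    inform(paste0("Dropped ", n_out, " out-of-window visit row(s)."))
  }
  if (config$dedupe_visits) {
    n0 <- nrow(visits)
    visits <- dplyr::distinct(visits)
    if (nrow(visits) < n0) {
      inform(paste0("Collapsed ", n0 - nrow(visits), " duplicate visit row(s)."))
    }
  }
  attr(visits, "rejected") <- rejected
  visits
}

#' Read the physician roster
#'
#' @param path Path to a CSV with columns `physician_id`, `specialty` and
#'   optionally `age`, `municipality`.
#' @return A tibble with columns `physician_id`, `specialty`, `age`,
#'   `municipality`.
#' @export
read_physicians <- function(path) {
  if (!file.exists(path)) abort(paste0("File not found: ", path))
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  required <- c("physician_id", "specialty")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols) > 0) {
    abort(paste0("Physician file is missing required column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  tibble::tibble(
    physician_id = raw$physician_id,
    specialty = raw$specialty,
    age = if ("age" %in% names(raw)) suppressWarnings(as.numeric(raw$age)) else NA_real_,
    municipality = if ("municipality" %in% names(raw)) raw$municipality else NA_character_
  )
}

#' Read the patient table
#'
#' @param path Path to a CSV with columns `patient_id` and `comorbidity_count`
#'   (chronic conditions per the insurer's classification, taken as given).
#' @return A tibble with columns `patient_id`, `comorbidity_count` (integer).
#' @export
read_patients <- function(path) {
  if (!file.exists(path)) abort(paste0("File not found: ", path))
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  required <- c("patient_id", "comorbidity_count")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols) > 0) {
    abort(paste0("Patient file is missing required column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  cc <- suppressWarnings(as.integer(raw$comorbidity_count))
  if (any(is.na(cc)) || any(cc < 0)) {
    abort("`comorbidity_count` must be a non-negative integer for every patient.")
  }
  tibble::tibble(patient_id = raw$patient_id, comorbidity_count = cc)
}

#' Write claims tables to CSV
#'
#' Inverse of the readers; a written table re-reads field-by-field identical.
#'
#' @param visits,physicians,patients Tibbles as returned by the readers or by
#'   [simulate_claims()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_visits <- function(visits, path) {
  out <- dplyr::select(visits, dplyr::any_of(c("patient_id", "physician_id",
                                               "visit_date", "satisfaction")))
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_visits
#' @export
write_physicians <- function(physicians, path) {
  out <- dplyr::select(physicians, dplyr::any_of(c("physician_id", "specialty",
                                                   "age", "municipality")))
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_visits
#' @export
write_patients <- function(patients, path) {
  out <- dplyr::select(patients, dplyr::any_of(c("patient_id", "comorbidity_count")))
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' Cross-validate the three claims tables
#'
#' Report-only consistency check: visits must reference known physicians and
#' patients, roster ids must be unique, and specialties must be non-empty. The
#' dataset passes if and only if every list in the report is empty.
#'
#' @param visits,physicians,patients The three claims tibbles.
#' @return A list of class `"claims_validation"` with tibbles
#'   `orphan_physician_visits`, `orphan_patient_visits`,
#'   `duplicate_physicians`, `empty_specialties` and a logical `is_valid`.
#' @export
validate_claims <- function(visits, physicians, patients) {
  orphan_phys <- dplyr::filter(visits, !.data$physician_id %in% physicians$physician_id)
  orphan_pat <- dplyr::filter(visits, !.data$patient_id %in% patients$patient_id)
  dup <- physicians |>
    dplyr::count(.data$physician_id, name = "n_rows") |>
    dplyr::filter(.data$n_rows > 1)
  empty_spec <- dplyr::filter(physicians,
                              is.na(.data$specialty) | .data$specialty == "")
  out <- list(
    orphan_physician_visits = orphan_phys,
    orphan_patient_visits = orphan_pat,
    duplicate_physicians = dup,
    empty_specialties = empty_spec,
    is_valid = nrow(orphan_phys) == 0 && nrow(orphan_pat) == 0 &&
      nrow(dup) == 0 && nrow(empty_spec) == 0
  )
  class(out) <- "claims_validation"
  out
}

#' @export
print.claims_validation <- function(x, ...) {
  cat("<claims_validation>", if (x$is_valid) "PASS" else "FAIL", "\n")
  cat("  orphan physician visits:", nrow(x$orphan_physician_visits), "\n")
  cat("  orphan patient visits  :", nrow(x$orphan_patient_visits), "\n")
  cat("  duplicate roster ids   :", nrow(x$duplicate_physicians), "\n")
  cat("  empty specialties      :", nrow(x$empty_specialties), "\n")
  invisible(x)
}

#' Write a validation report as JSON
#'
#' @param report A `"claims_validation"` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_validation_report <- function(report, path) {
  stopifnot(inherits(report, "claims_validation"))
  jsonlite::write_json(
    list(
      is_valid = report$is_valid,
      orphan_physician_visits = report$orphan_physician_visits,
      orphan_patient_visits = report$orphan_patient_visits,
      duplicate_physicians = report$duplicate_physicians,
      empty_specialties = report$empty_specialties
    ),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}
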