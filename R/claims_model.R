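# Claims data model: a bundle of one patient table plus one event table is
# the input contract for the whole pipeline. One event row is one dated,
# code-system-tagged claim line (diagnosis, procedure or drug delivery).

PATIENT_COLS <- c("patient_id", "sex", "birth_date", "insurance_plan",
                  "vital_status", "death_date", "inclusion_date")
EVENT_COLS <- c("patient_id", "event_date", "code_system", "code",
                "care_context")
CODE_SYSTEMS <- c("ICD10", "CCAM", "ATC", "LTI_ICD10")

#' Construct a claims bundle
#'
#' Bundles a patient table and an event table after validating the data
#' model invariants: complete columns, known factor levels, death date
#' present exactly for deceased patients and never before birth, non-empty
#' codes, and referential integrity of `events$patient_id`. Events are
#' stored sorted by patient and date, so bundle equality is insensitive to
#' input row order.
#'
#' @param patients tibble with columns `patient_id`, `sex`
#'   (`"female"`/`"male"`), `birth_date`, `insurance_plan`
#'   (`"general"`/`"other"`), `vital_status` (`"alive"`/`"dead"`),
#'   `death_date` (`NA` when alive), `inclusion_date`. Dates are `Date` or
#'   ISO-8601 strings.
#' @param events tibble with columns `patient_id`, `event_date`,
#'   `code_system` (ICD10/CCAM/ATC/LTI_ICD10), `code`, `care_context`
#'   (`"hospital"`/`"outpatient"`).
#' @return an object of class `claims_bundle`: a list with elements
#'   `patients` and `events` (tibbles).
#' @export
#' @examples
#' b <- claims_bundle(
#'   tibble::tibble(patient_id = "p1", sex = "female",
#'                  birth_date = "1960-05-01", insurance_plan = "general",
#'                  vital_status = "alive", death_date = NA,
#'                  inclusion_date = "2013-02-01"),
#'   tibble::tibble(patient_id = "p1", event_date = "2013-02-01",
#'                  code_system = "ICD10", code = "C50",
#'                  care_context = "hospital"))
#' b
claims_bundle <- function(patients, events) {
  patients <- tibble::as_tibble(patients)
  events <- tibble::as_tibble(events)

  miss_p <- setdiff(PATIENT_COLS, names(patients))
  if (length(miss_p)) {
    abort_ctx(paste0("patients table missing column(s): ",
                     paste(miss_p, collapse = ", ")), "schema_error")
  }
  miss_e <- setdiff(EVENT_COLS, names(events))
  if (length(miss_e)) {
    abort_ctx(paste0("events table missing column(s): ",
                     paste(miss_e, collapse = ", ")), "schema_error")
  }

  patients$birth_date <- as_date_safe(patients$birth_date)
  patients$death_date <- as_date_safe(patients$death_date)
  patients$inclusion_date <- as_date_safe(patients$inclusion_date)
  events$event_date <- as_date_safe(events$event_date)

  if (anyDuplicated(patients$patient_id)) {
    abort_ctx("duplicate patient_id in patients table", "schema_error")
  }
  bad_sex <- !patients$sex %in% c("female", "male")
  if (any(bad_sex)) abort_ctx("sex must be 'female' or 'male'", "schema_error")
  if (!all(patients$insurance_plan %in% c("general", "other"))) {
    abort_ctx("insurance_plan must be 'general' or 'other'", "schema_error")
  }
  if (!all(patients$vital_status %in% c("alive", "dead"))) {
    abort_ctx("vital_status must be 'alive' or 'dead'", "schema_error")
  }
  # death date present iff deceased, and never before birth
  dead <- patients$vital_status == "dead"
  if (any(dead & is.na(patients$death_date))) {
    abort_ctx("deceased patient without death_date", "schema_error")
  }
  if (any(!dead & !is.na(patients$death_date))) {
    abort_ctx("death_date present for a patient recorded alive",
              "schema_error")
  }
  if (any(dead & patients$death_date < patients$birth_date, na.rm = TRUE)) {
    abort_ctx("death_date before birth_date", "schema_error")
  }

  if (nrow(events)) {
    if (any(is.na(events$code) | events$code == "")) {
      abort_ctx("event with empty code", "schema_error")
    }
    if (!all(events$code_system %in% CODE_SYSTEMS)) {
      abort_ctx(paste0("code_system must be one of ",
                       paste(CODE_SYSTEMS, collapse = ", ")), "schema_error")
    }
    if (!all(events$care_context %in% c("hospital", "outpatient"))) {
      abort_ctx("care_context must be 'hospital' or 'outpatient'",
                "schema_error")
    }
    orphan <- setdiff(unique(events$patient_id), patients$patient_id)
    if (length(orphan)) {
      abort_ctx(paste0("event(s) reference unknown patient_id: ",
                       paste(utils::head(orphan, 5), collapse = ", ")),
                "referential_error")
    }
    events <- dplyr::arrange(events, .data$patient_id, .data$event_date,
                             .data$code_system, .data$code)
  }
  patients <- dplyr::arrange(patients, .data$patient_id)

  structure(list(patients = patients, events = events),
            class = "claims_bundle")
}

#' @export
print.claims_bundle <- function(x, ...) {
  cat("<claims_bundle> ", nrow(x$patients), " patients, ",
      nrow(x$events), " events\n", sep = "")
  rep <- attr(x, "load_report")
  if (!is.null(rep) && nrow(rep)) {
    cat("  load report: ", sum(rep$n), " event row(s) with codes absent",
        " from the dictionary\n", sep = "")
  }
  invisible(x)
}

read_table_any <- function(path, col_types) {
  if (grepl("\\.parquet$", path)) {
    if (!requireNamespace("arrow", quietly = TRUE)) {
      abort_ctx("reading Parquet requires the 'arrow' package", "io_error")
    }
    return(tibble::as_tibble(arrow::read_parquet(path)))
  }
  readr::read_csv(path, col_types = col_types, progress = FALSE)
}

#' Read a claims bundle from disk
#'
#' Reads `patients.csv` and `events.csv` (Parquet mirrors with the same
#' schema are accepted by extension) from a directory or from explicitly
#' named paths, validates the bundle, and attaches a load report listing
#' event codes that are absent from every dictionary set. Unknown codes are
#' retained, never dropped; unparseable dates raise an error naming the
#' offending rows.
#'
#' @param path directory containing `patients.csv`/`events.csv`, or a named
#'   list/vector with elements `patients` and `events`.
#' @param dictionary a `code_dictionary` used to flag unknown codes.
#' @return a `claims_bundle` with attribute `load_report`, a tibble with
#'   columns `code_system`, `code`, `n` (one row per unknown code).
#' @export
read_claims <- function(path, dictionary = default_code_dictionary()) {
  if (length(path) == 1 && is.character(path) && dir.exists(path)) {
    paths <- list(patients = file.path(path, "patients.csv"),
                  events = file.path(path, "events.csv"))
  } else {
    paths <- as.list(path)
  }
  if (!all(c("patients", "events") %in% names(paths))) {
    abort_ctx("path must name both a patients and an events table",
              "io_error")
  }
  for (p in unlist(paths)) {
    if (!file.exists(p)) abort_ctx(paste0("file not found: ", p), "io_error")
  }

  patients <- read_table_any(paths$patients, readr::cols(
    patient_id = readr::col_character(), sex = readr::col_character(),
    birth_date = readr::col_character(),
    insurance_plan = readr::col_character(),
    vital_status = readr::col_character(),
    death_date = readr::col_character(),
    inclusion_date = readr::col_character()))
  events <- read_table_any(paths$events, readr::cols(
    patient_id = readr::col_character(),
    event_date = readr::col_character(),
    code_system = readr::col_character(), code = readr::col_character(),
    care_context = readr::col_character()))

  check_dates <- function(raw, parsed, col, what) {
    bad <- which(!is.na(raw) & raw != "" & is.na(parsed))
    if (length(bad)) {
      abort_ctx(paste0("unparseable ", col, " in ", what, " row(s) ",
                       paste(utils::head(bad, 5), collapse = ", ")),
                "parse_error")
    }
  }
  for (col in c("birth_date", "death_date", "inclusion_date")) {
    parsed <- as_date_safe(patients[[col]])
    check_dates(patients[[col]], parsed, col, "patients")
    patients[[col]] <- parsed
  }
  parsed <- as_date_safe(events$event_date)
  check_dates(events$event_date, parsed, "event_date", "events")
  events$event_date <- parsed

  bundle <- claims_bundle(patients, events)
  known <- all_dictionary_codes(dictionary)
  unknown <- bundle$events[!event_keys(bundle$events) %in% known, ,
                          drop = FALSE]
  report <- dplyr::count(unknown, .data$code_system, .data$code, name = "n")
  attr(bundle, "load_report") <- report
  bundle
}

#' Write a claims bundle to disk
#'
#' Writes `patients.csv` and `events.csv` under `dir`. Absent optional
#' dates are written as empty fields (never a sentinel string), so
#' `read_claims(write_claims(b))` reproduces `b` field for field.
#'
#' @param bundle a `claims_bundle`.
#' @param dir output directory (created if needed).
#' @return the directory path, invisibly.
#' @export
write_claims <- function(bundle, dir) {
  stopifnot(inherits(bundle, "claims_bundle"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(bundle$patients, file.path(dir, "patients.csv"),
                   na = "")
  readr::write_csv(bundle$events, file.path(dir, "events.csv"), na = "")
  invisible(dir)
}
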