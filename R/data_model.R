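#' Construct an EMR cohort object
#'
#' The in-memory representation of an outpatient EMR extract: three linked
#' tables keyed by `patient_id`. Event tables are sorted by patient and date.
#'
#' @param patients Tibble with columns `patient_id` (non-empty, unique),
#'   `birth_year` (integer), `gender` (`"female"`, `"male"`,
#'   `"unspecified"`) and `documented_si_note` (logical; structured stand-in
#'   for a documented intolerance/toxicity/allergy note).
#' @param diagnoses Tibble with `patient_id`, `date` (Date), `icd10`.
#' @param prescriptions Tibble with `patient_id`, `date` (Date), `atc`,
#'   `molecule` (normalised lowercase), `dose_mg` (positive or NA) and
#'   `days_supplied` (positive integer or NA).
#'
#' @return An `emr_cohort` list of the three tibbles.
#' @export
emr_cohort <- function(patients, diagnoses, prescriptions) {
  patients <- tibble::as_tibble(patients)
  diagnoses <- dplyr::arrange(tibble::as_tibble(diagnoses), .data$patient_id, .data$date)
  prescriptions <- dplyr::arrange(tibble::as_tibble(prescriptions), .data$patient_id, .data$date)
  structure(list(patients = patients, diagnoses = diagnoses,
                 prescriptions = prescriptions),
            class = "emr_cohort")
}

#' @export
print.emr_cohort <- function(x, ...) {
  cat(sprintf("<emr_cohort> %d patients, %d diagnoses, %d prescriptions\n",
              nrow(x$patients), nrow(x$diagnoses), nrow(x$prescriptions)))
  invisible(x)
}

emr_schemas <- list(
  patients = c("patient_id", "birth_year", "gender", "documented_si_note"),
  diagnoses = c("patient_id", "date", "icd10"),
  prescriptions = c("patient_id", "date", "atc", "molecule", "dose_mg",
                    "days_supplied")
)

icd10_pattern <- "^[A-Z][0-9]{2}(\\.[0-9A-Z]{1,2})?$"

#' Read an EMR extract from delimited text
#'
#' Loads `patients.csv`, `diagnoses.csv` and `prescriptions.csv` from a
#' directory (or explicit paths). Dates must be ISO-8601 (`YYYY-MM-DD`); rows
#' whose date does not parse are dropped and counted in the load report.
#' Exact-duplicate prescription rows (same patient, date, ATC code and dose)
#' are collapsed to one, with the removed count reported.
#'
#' @param dir Directory containing the three CSV files; alternatively supply
#'   `paths`, a named list/vector with elements `patients`, `diagnoses`,
#'   `prescriptions`.
#' @param paths Optional explicit file paths (overrides `dir`).
#' @return An [emr_cohort()] with attribute `load_report`, a list with
#'   `dropped_dates` (rows removed per table) and `deduplicated_prescriptions`.
#' @export
read_emr <- function(dir = NULL, paths = NULL) {
  if (is.null(paths)) {
    assert_that(!is.null(dir), "supply `dir` or `paths`")
    paths <- list(patients = file.path(dir, "patients.csv"),
                  diagnoses = file.path(dir, "diagnoses.csv"),
                  prescriptions = file.path(dir, "prescriptions.csv"))
  }
  for (p in unlist(paths)) assert_that(file.exists(p), paste0("missing file: ", p))

  read_one <- function(path, table) {
    df <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                          progress = FALSE)
    missing <- setdiff(emr_schemas[[table]], names(df))
    assert_that(length(missing) == 0,
                paste0(table, ".csv missing required column(s): ",
                       paste(missing, collapse = ", ")))
    df[emr_schemas[[table]]]
  }

  pats <- read_one(paths$patients, "patients")
  diag <- read_one(paths$diagnoses, "diagnoses")
  rx <- read_one(paths$prescriptions, "prescriptions")

  pats$birth_year <- as.integer(pats$birth_year)
  pats$documented_si_note <- tolower(pats$documented_si_note) %in% c("true", "1", "t")
  assert_that(!anyDuplicated(pats$patient_id) && !any(is.na(pats$patient_id) | pats$patient_id == ""),
              "patient_id must be non-empty and unique in patients.csv")

  dropped <- c(patients = 0L, diagnoses = 0L, prescriptions = 0L)
  parse_dates <- function(df, table) {
    d <- as.Date(df$date, format = "%Y-%m-%d")
    bad <- is.na(d) | d < as.Date("1900-01-01") | d >= as.Date("2100-01-01")
    dropped[[table]] <<- sum(bad)
    df$date <- d
    df[!bad, , drop = FALSE]
  }
  diag <- parse_dates(diag, "diagnoses")
  rx <- parse_dates(rx, "prescriptions")

  rx$dose_mg <- suppressWarnings(as.numeric(rx$dose_mg))
  rx$days_supplied <- suppressWarnings(as.integer(rx$days_supplied))
  n_before <- nrow(rx)
  rx <- dplyr::distinct(rx, .data$patient_id, .data$date, .data$atc,
                        .data$dose_mg, .keep_all = TRUE)
  n_dedup <- n_before - nrow(rx)

  out <- emr_cohort(pats, diag, rx)
  attr(out, "load_report") <- list(dropped_dates = dropped,
                                   deduplicated_prescriptions = n_dedup)
  out
}

#' Write an EMR cohort to delimited text
#'
#' Inverse of [read_emr()]: writing then reading restores the cohort up to
#' row order. Absent doses/supplies are written as empty fields.
#'
#' @param cohort An [emr_cohort()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the three file paths.
#' @export
write_emr <- function(cohort, dir) {
  assert_that(inherits(cohort, "emr_cohort"), "cohort must be an emr_cohort")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(patients = file.path(dir, "patients.csv"),
                diagnoses = file.path(dir, "diagnoses.csv"),
                prescriptions = file.path(dir, "prescriptions.csv"))
  readr::write_csv(cohort$patients, paths$patients, progress = FALSE)
  readr::write_csv(cohort$diagnoses, paths$diagnoses, progress = FALSE)
  readr::write_csv(cohort$prescriptions, paths$prescriptions, progress = FALSE)
  invisible(paths)
}

#' Validate an EMR cohort against its schema invariants
#'
#' Checks patient-id integrity, ICD-10 code shape, date range, positive doses,
#' and referential integrity of the event tables.
#'
#' @param cohort An [emr_cohort()].
#' @return A tibble of issues (`table`, `check`, `n`); zero rows when valid.
#' @export
validate_emr <- function(cohort) {
  issues <- list()
  note <- function(table, check, n) {
    if (n > 0) issues[[length(issues) + 1L]] <<- tibble::tibble(
      table = table, check = check, n = as.integer(n))
  }
  p <- cohort$patients
  note("patients", "empty patient_id", sum(is.na(p$patient_id) | p$patient_id == ""))
  note("patients", "duplicate patient_id", sum(duplicated(p$patient_id)))
  note("patients", "gender not in {female, male, unspecified}",
       sum(!p$gender %in% c("female", "male", "unspecified")))
  d <- cohort$diagnoses
  note("diagnoses", "malformed icd10", sum(!grepl(icd10_pattern, d$icd10)))
  note("diagnoses", "unknown patient_id", sum(!d$patient_id %in% p$patient_id))
  rx <- cohort$prescriptions
  note("prescriptions", "non-positive dose_mg",
       sum(!is.na(rx$dose_mg) & rx$dose_mg <= 0))
  note("prescriptions", "empty atc", sum(is.na(rx$atc) | rx$atc == ""))
  note("prescriptions", "unknown patient_id", sum(!rx$patient_id %in% p$patient_id))
  for (tb in c("diagnoses", "prescriptions")) {
    dd <- cohort[[tb]]$date
    note(tb, "date out of range",
         sum(dd < as.Date("1900-01-01") | dd >= as.Date("2100-01-01")))
  }
  if (length(issues) == 0) {
    tibble::tibble(table = character(), check = character(), n = integer())
  } else {
    dplyr::bind_rows(issues)
  }
}
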