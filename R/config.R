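#' Study design configuration
#'
#' Bundles the study window, selection window, lookback length, the
#' discontinuation gap, and the editable ICD-10 / ATC code sets that drive
#' cohort selection, subgroup tagging and event detection. All date intervals
#' in the package are half-open `[start, end)`.
#'
#' @param study_start,study_end Study period (default March 2017 to March
#'   2020). Prescriptions and diagnoses outside `[study_start, study_end)` are
#'   ignored by the analysis.
#' @param selection_start,selection_end Selection period within which every
#'   cohort member must have at least one consultation (default March 2019 to
#'   March 2020).
#' @param lookback_days Maximum lookback from the index date, in days
#'   (default 730); the lookback never starts before `study_start`.
#' @param gap_days A gap of strictly more than this many days between the end
#'   of prescription coverage and the next prescription (or the study end)
#'   counts as discontinuation (default 180).
#' @param days_supplied_default Days of coverage assumed for a prescription
#'   with no recorded supply (default 30, the typical outpatient script).
#' @param mpr_threshold Medication-possession-ratio cutoff below which a
#'   statin history with at least three scripts counts as intermittent dosing
#'   (default 0.5).
#' @param code_sets Named list of ICD-10 prefix vectors; must contain
#'   `ascvd`, `high_cv_risk`, `hypercholesterolemia` and `sams`. Extra sets
#'   (e.g. risk factors) are carried through to the characteristics report.
#' @param atc_sets Named list of ATC prefix vectors; must contain `llt` and
#'   `statin`.
#' @param intensity_map Statin intensity banding, see [default_intensity_map()].
#' @param lowest_dose Named numeric vector: lowest marketed daily dose (mg)
#'   per statin molecule.
#'
#' @return A `study_config` list.
#' @export
study_config <- function(study_start = as.Date("2017-03-01"),
                         study_end = as.Date("2020-03-31"),
                         selection_start = as.Date("2019-03-01"),
                         selection_end = as.Date("2020-03-31"),
                         lookback_days = 730L,
                         gap_days = 180L,
                         days_supplied_default = 30L,
                         mpr_threshold = 0.5,
                         code_sets = default_code_sets(),
                         atc_sets = default_atc_sets(),
                         intensity_map = default_intensity_map(),
                         lowest_dose = default_lowest_dose()) {
  study_start <- as_iso_date(study_start); study_end <- as_iso_date(study_end)
  selection_start <- as_iso_date(selection_start)
  selection_end <- as_iso_date(selection_end)
  assert_that(study_start < selection_start, "study_start must precede selection_start")
  assert_that(selection_start < selection_end, "selection_start must precede selection_end")
  assert_that(selection_end <= study_end, "selection_end must not exceed study_end")
  assert_that(gap_days > 0, "gap_days must be positive")
  assert_that(lookback_days > 0, "lookback_days must be positive")
  needed <- c("ascvd", "high_cv_risk", "hypercholesterolemia", "sams")
  missing <- setdiff(needed, names(code_sets))
  assert_that(length(missing) == 0,
              paste0("code_sets missing: ", paste(missing, collapse = ", ")))
  assert_that(all(c("llt", "statin") %in% names(atc_sets)),
              "atc_sets must contain 'llt' and 'statin'")
  structure(list(
    study_start = study_start, study_end = study_end,
    selection_start = selection_start, selection_end = selection_end,
    lookback_days = as.integer(lookback_days), gap_days = as.integer(gap_days),
    days_supplied_default = as.integer(days_supplied_default),
    mpr_threshold = mpr_threshold,
    code_sets = code_sets, atc_sets = atc_sets,
    intensity_map = intensity_map, lowest_dose = lowest_dose
  ), class = "study_config")
}

#' Default ICD-10 code prefix sets
#'
#' Conventional stand-ins for the qualifying-diagnosis and event code lists;
#' every set is overridable through [study_config()]. SAMS covers myalgia
#' (M79.1), myositis (M60.8/M60.9), drug-induced and unspecified myopathy
#' (G72.0/G72.9) and muscle cramps/spasms (R25.2).
#'
#' @return Named list of character vectors of ICD-10 prefixes.
#' @export
default_code_sets <- function() {
  list(
    ascvd = c("I20", "I21", "I22", "I23", "I24", "I25", "I63", "I65", "I66",
              "I70", "I73.9"),
    high_cv_risk = c("E10", "E11"),
    hypercholesterolemia = c("E78.0", "E78.2", "E78.4", "E78.5"),
    sams = c("M79.1", "M60.8", "M60.9", "G72.0", "G72.9", "R25.2"),
    sams_myalgia = "M79.1",
    sams_myositis = c("M60.8", "M60.9"),
    sams_myopathy = c("G72.0", "G72.9"),
    sams_cramps = "R25.2",
    obesity = "E66",
    vitamin_d_deficiency = "E55",
    hypothyroidism = "E03",
    liver_disease = c("K70", "K71", "K72", "K73", "K74", "K75", "K76", "K77"),
    ckd = c("N18.3", "N18.4", "N18.5"),
    alcohol_abuse = "F10"
  )
}

#' Default ATC code prefix sets
#'
#' @return Named list of character vectors of ATC prefixes. `llt` is all
#'   lipid-modifying agents (C10), `statin` the HMG-CoA reductase inhibitors
#'   (plain C10AA and the statin-containing fixed-dose combinations C10B),
#'   plus sets used by the characteristics report.
#' @export
default_atc_sets <- function() {
  list(
    llt = "C10",
    statin = c("C10AA", "C10BA", "C10BX"),
    ezetimibe = c("C10AX09", "C10BA02"),
    fibrate = "C10AB",
    antibiotics_ddi = "J01FA",
    verapamil_diltiazem = c("C08DA01", "C08DB01"),
    amiodarone = "C01BD01"
  )
}

#' Default statin intensity banding
#'
#' Conventional low / moderate / high intensity classes by molecule and daily
#' dose band (mg). Doses falling outside every band for a molecule are
#' assigned the nearest band's class (ties resolve to the lower intensity).
#'
#' @return A tibble with columns `molecule`, `dose_min`, `dose_max`,
#'   `intensity`.
#' @export
default_intensity_map <- function() {
  tibble::tribble(
    ~molecule,      ~dose_min, ~dose_max, ~intensity,
    "simvastatin",        10,        10,  "low",
    "simvastatin",        20,        40,  "moderate",
    "simvastatin",        80,        80,  "high",
    "atorvastatin",       10,        20,  "moderate",
    "atorvastatin",       40,        80,  "high",
    "rosuvastatin",        5,        10,  "moderate",
    "rosuvastatin",       20,        40,  "high",
    "pravastatin",        10,        20,  "low",
    "pravastatin",        40,        80,  "moderate",
    "fluvastatin",        20,        40,  "low",
    "fluvastatin",        80,        80,  "moderate",
    "lovastatin",         20,        20,  "low",
    "lovastatin",         40,        80,  "moderate",
    "pitavastatin",        1,         1,  "low",
    "pitavastatin",        2,         4,  "moderate"
  )
}

#' Default lowest marketed daily dose per statin molecule (mg)
#' @return Named numeric vector.
#' @export
default_lowest_dose <- function() {
  c(simvastatin = 10, atorvastatin = 10, rosuvastatin = 5, pravastatin = 10,
    fluvastatin = 20, lovastatin = 20, pitavastatin = 1)
}

intensity_levels <- c("low", "moderate", "high")

# Intensity class for vectors of (molecule, dose). Unknown molecule -> error.
statin_intensity <- function(molecule, dose_mg, intensity_map = default_intensity_map()) {
  unknown <- setdiff(unique(molecule), unique(intensity_map$molecule))
  assert_that(length(unknown) == 0,
              paste0("no intensity banding for molecule(s): ",
                     paste(unknown, collapse = ", ")))
  out <- character(length(molecule))
  for (m in unique(molecule)) {
    idx <- which(molecule == m)
    bands <- intensity_map[intensity_map$molecule == m, ]
    bands <- bands[order(match(bands$intensity, intensity_levels)), ]
    for (i in idx) {
      d <- dose_mg[i]
      if (is.na(d)) { out[i] <- NA_character_; next }
      hit <- which(d >= bands$dose_min & d <= bands$dose_max)
      if (length(hit) > 0) {
        out[i] <- bands$intensity[hit[1]]
      } else {
        gap <- pmax(bands$dose_min - d, d - bands$dose_max, 0)
        out[i] <- bands$intensity[which.min(gap)]
      }
    }
  }
  factor(out, levels = intensity_levels, ordered = TRUE)
}
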