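# Shared fixtures: hand-built exposures, one-patient cohorts and rule profiles.

# A single-patient exposure tibble in the shape produced by build_exposure().
mk_exposure <- function(dates, molecule, dose_mg, days_supplied = 30L,
                        patient_id = "P1", config = study_config()) {
  tibble::tibble(
    patient_id = patient_id,
    date = as.Date(dates),
    molecule = molecule,
    dose_mg = dose_mg,
    intensity = sipheno:::statin_intensity(molecule, dose_mg,
                                           config$intensity_map),
    days_supplied = as.integer(days_supplied))
}

# Minimal cohort with sensible defaults; all arguments optional.
mk_cohort <- function(patients = NULL, diagnoses = NULL, prescriptions = NULL) {
  if (is.null(patients)) {
    patients <- tibble::tibble(
      patient_id = "P1", birth_year = 1950L, gender = "female",
      documented_si_note = FALSE)
  }
  if (is.null(diagnoses)) {
    diagnoses <- tibble::tibble(patient_id = character(),
                                date = as.Date(character()),
                                icd10 = character())
  }
  if (is.null(prescriptions)) {
    prescriptions <- tibble::tibble(
      patient_id = character(), date = as.Date(character()),
      atc = character(), molecule = character(), dose_mg = numeric(),
      days_supplied = integer())
  }
  emr_cohort(patients, diagnoses, prescriptions)
}

mk_rx <- function(patient_id, dates, molecule, dose_mg, days_supplied = 30L) {
  atc_map <- c(simvastatin = "C10AA01", lovastatin = "C10AA02",
               pravastatin = "C10AA03", fluvastatin = "C10AA04",
               atorvastatin = "C10AA05", rosuvastatin = "C10AA07",
               pitavastatin = "C10AA08", ezetimibe = "C10AX09",
               fenofibrate = "C10AB05")
  tibble::tibble(patient_id = patient_id, date = as.Date(dates),
                 atc = unname(atc_map[molecule]), molecule = molecule,
                 dose_mg = dose_mg, days_supplied = as.integer(days_supplied))
}

# Event profile with every flag off; override fields by name.
base_profile <- function(...) {
  p <- list(down_titration_same = FALSE, down_titration_diff = FALSE,
            switch = FALSE, multi_statin = FALSE,
            permanent_discontinuation = FALSE, prior_discontinuation = FALSE,
            intermittent = FALSE, low_dose = FALSE,
            low_intensity_only = FALSE, sams = FALSE, documented_si = FALSE)
  mods <- list(...)
  p[names(mods)] <- mods
  p
}

# Exhaustive-sweep oracle for find_threshold(): evaluates precision and recall
# at every candidate cut and returns the minimum achievable |P - R| and the
# lowest threshold achieving it.
threshold_oracle <- function(scores, labels) {
  u <- sort(unique(scores))
  candidates <- c(u[1] - 1e-9,
                  if (length(u) > 1) (u[-1] + u[-length(u)]) / 2,
                  u[length(u)] + 1e-9)
  npos <- sum(labels == 1)
  gaps <- vapply(candidates, function(t) {
    pred <- scores >= t
    tp <- sum(pred & labels == 1)
    p <- if (sum(pred) == 0) 1 else tp / sum(pred)
    abs(p - tp / npos)
  }, numeric(1))
  list(gap = min(gaps), threshold = candidates[which(gaps <= min(gaps) + 1e-12)][1],
       candidates = candidates, gaps = gaps)
}
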