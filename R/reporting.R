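#' Patient and treatment characteristics by classification column
#'
#' Tabulates the standard characteristics rows — age bands (18-30, 30-50,
#' 50-70, 70+), gender, qualifying subgroups, comorbid risk factors, statin
#' molecules used, non-statin lipid-lowering therapy, the individual
#' statin-associated muscle symptom conditions and drug-drug-interaction drug
#' classes — against the five classification labels plus a total column.
#' Code-presence rows count a patient once if any event in the lookback
#' window matches the configured prefix set. Percentages are per column
#' (half-up, one decimal).
#'
#' @param cohort An [emr_cohort()].
#' @param entries Entries tibble from [select_cohort()].
#' @param classifications Classification tibble from [classify_cohort()].
#' @param config A [study_config()].
#' @return Tidy tibble `section`, `characteristic`, `column`, `count`, `pct`.
#' @export
characteristics_table <- function(cohort, entries, classifications,
                                  config = study_config()) {
  base <- dplyr::inner_join(entries,
                            classifications[c("patient_id", "label")],
                            by = "patient_id")
  base <- dplyr::left_join(base, cohort$patients[c("patient_id", "gender")],
                           by = "patient_id")
  cols <- c(si_labels(), "total")
  col_n <- c(table(base$label)[si_labels()], total = nrow(base))

  win <- entries[c("patient_id", "lookback_start")]
  dg <- dplyr::inner_join(cohort$diagnoses, win, by = "patient_id")
  dg <- dplyr::filter(dg, .data$date >= .data$lookback_start,
                      .data$date < config$study_end)
  rx <- dplyr::inner_join(cohort$prescriptions, win, by = "patient_id")
  rx <- dplyr::filter(rx, .data$date >= .data$lookback_start,
                      .data$date < config$study_end)

  rows <- list()
  add_flag <- function(section, characteristic, flagged_ids) {
    has <- base$patient_id %in% flagged_ids
    cnt <- c(tapply(has, base$label, sum, default = 0L)[si_labels()],
             total = sum(has))
    rows[[length(rows) + 1L]] <<- tibble::tibble(
      section = section, characteristic = characteristic, column = cols,
      count = as.integer(cnt),
      pct = round_half_up(100 * as.numeric(cnt) / pmax(col_n, 1), 1))
  }

  bands <- cut(base$age_at_index, c(18, 30, 50, 70, Inf), right = FALSE,
               labels = c("18-30", "30-50", "50-70", "70+"))
  for (b in levels(bands)) {
    add_flag("age", b, base$patient_id[!is.na(bands) & bands == b])
  }
  for (gnd in c("female", "male", "unspecified")) {
    add_flag("gender", gnd, base$patient_id[base$gender == gnd])
  }
  for (s in c("ascvd", "high_cv_risk", "hypercholesterolemia")) {
    add_flag("subgroup", s, base$patient_id[base[[s]]])
  }
  risk_sets <- c("obesity", "vitamin_d_deficiency", "hypothyroidism",
                 "liver_disease", "ckd", "alcohol_abuse")
  for (rs in intersect(risk_sets, names(config$code_sets))) {
    add_flag("risk_factor", rs,
             dg$patient_id[matches_prefix(dg$icd10, config$code_sets[[rs]])])
  }
  statin_rx <- rx[matches_prefix(rx$atc, config$atc_sets$statin), ]
  for (mol in sort(unique(statin_rx$molecule))) {
    add_flag("statin", mol, statin_rx$patient_id[statin_rx$molecule == mol])
  }
  for (ns in intersect(c("ezetimibe", "fibrate"), names(config$atc_sets))) {
    add_flag("non_statin", ns,
             rx$patient_id[matches_prefix(rx$atc, config$atc_sets[[ns]])])
  }
  sams_rows <- c("sams_myalgia", "sams_myositis", "sams_myopathy", "sams_cramps")
  for (sr in intersect(sams_rows, names(config$code_sets))) {
    add_flag("sams", sub("^sams_", "", sr),
             dg$patient_id[matches_prefix(dg$icd10, config$code_sets[[sr]])])
  }
  ddi <- c("antibiotics_ddi", "verapamil_diltiazem", "amiodarone")
  for (dset in intersect(ddi, names(config$atc_sets))) {
    add_flag("drug_drug", dset,
             rx$patient_id[matches_prefix(rx$atc, config$atc_sets[[dset]])])
  }
  dplyr::bind_rows(rows)
}

#' First-event down-titration and switch transition matrices
#'
#' Counts each patient's first down-titration and first switch transition as
#' (from molecule/dose) to (to molecule/dose) cells, split by classification
#' label; a patient contributes at most one cell per matrix.
#'
#' @param profiles Profile tibble from [build_event_profiles()].
#' @param classifications Classification tibble from [classify_cohort()]
#'   (optional; when missing, all patients are pooled).
#' @return List with `down_titration` and `switch`: tidy tibbles
#'   `from_molecule`, `from_dose`, `to_molecule`, `to_dose`, `label`, `n`.
#' @export
transition_matrices <- function(profiles, classifications = NULL) {
  df <- profiles
  if (!is.null(classifications)) {
    df <- dplyr::left_join(df, classifications[c("patient_id", "label")],
                           by = "patient_id")
  } else {
    df$label <- "all"
  }
  tally <- function(prefix) {
    sub <- df[!is.na(df[[paste0(prefix, "_from_molecule")]]), ]
    if (nrow(sub) == 0) {
      return(tibble::tibble(from_molecule = character(), from_dose = numeric(),
                            to_molecule = character(), to_dose = numeric(),
                            label = character(), n = integer()))
    }
    out <- dplyr::count(
      sub,
      from_molecule = .data[[paste0(prefix, "_from_molecule")]],
      from_dose = .data[[paste0(prefix, "_from_dose")]],
      to_molecule = .data[[paste0(prefix, "_to_molecule")]],
      to_dose = .data[[paste0(prefix, "_to_dose")]],
      label = .data$label, name = "n")
    out
  }
  list(down_titration = tally("dt"), switch = tally("sw"))
}

#' Run the full phenotyping and calibration pipeline
#'
#' Orchestrates the end-to-end flow on an EMR extract directory: read,
#' eligibility and index dates, event detection, rule classification, feature
#' engineering, supervised calibration, and the report files. Writes
#' `attrition.csv`, `classifications.csv`, `prevalence.csv`,
#' `characteristics.csv`, `downtitration_matrix.csv`, `switch_matrix.csv`,
#' `model_report.json` and `manifest.json` to the output directory.
#' Deterministic for a fixed seed.
#'
#' @param input_dir Directory with `patients.csv`, `diagnoses.csv`,
#'   `prescriptions.csv`.
#' @param output_dir Directory for the result files (created if needed).
#' @param config A [study_config()].
#' @param seed Integer seed for the calibration stage.
#' @param n_tolerant,k_features,families,nrounds Passed to [calibrate_si()].
#' @return Invisibly, a list with `entries`, `attrition`, `profiles`,
#'   `classifications`, `counts`, `calibration`.
#' @export
run_pipeline <- function(input_dir, output_dir, config = study_config(),
                         seed = 1L, n_tolerant = 50000L, k_features = 400L,
                         families = c("logistic", "xgb_tree", "xgb_dart"),
                         nrounds = 50L) {
  cohort <- read_emr(input_dir)
  sel <- select_cohort(cohort, config)
  profiles <- build_event_profiles(cohort, sel$entries, config)
  cls <- classify_cohort(sel$entries, profiles)
  fm <- build_features(cohort, sel$entries, config)
  cal <- calibrate_si(fm, cls$classifications, n_tolerant = n_tolerant,
                      k_features = k_features, seed = seed,
                      families = families, nrounds = nrounds)
  chars <- characteristics_table(cohort, sel$entries, cls$classifications, config)
  mats <- transition_matrices(profiles, cls$classifications)

  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_csv(sel$attrition, file.path(output_dir, "attrition.csv"),
                   progress = FALSE)
  readr::write_csv(cls$classifications, file.path(output_dir, "classifications.csv"),
                   progress = FALSE)
  readr::write_csv(cal$prevalence, file.path(output_dir, "prevalence.csv"),
                   progress = FALSE)
  readr::write_csv(chars, file.path(output_dir, "characteristics.csv"),
                   progress = FALSE)
  readr::write_csv(mats$down_titration,
                   file.path(output_dir, "downtitration_matrix.csv"),
                   progress = FALSE)
  readr::write_csv(mats$switch, file.path(output_dir, "switch_matrix.csv"),
                   progress = FALSE)
  report <- lapply(cal$models, function(m) {
    rep <- m$reports[is.na(m$reports$fold), ]
    list(family = m$family,
         mean_f1 = rep$f1[rep$selected],
         mean_roc_auc = rep$roc_auc[rep$selected],
         mean_pr_auc = rep$pr_auc[rep$selected])
  })
  for (task in names(cal$thresholds)) {
    report[[task]]$threshold <- cal$thresholds[[task]]$threshold
    report[[task]]$precision <- cal$thresholds[[task]]$precision
    report[[task]]$recall <- cal$thresholds[[task]]$recall
  }
  jsonlite::write_json(report, file.path(output_dir, "model_report.json"),
                       auto_unbox = TRUE, digits = NA)
  manifest <- list(
    seed = seed,
    n_patients = nrow(cohort$patients),
    n_eligible = nrow(sel$entries),
    config_hash = rlang::hash(config),
    package_version = as.character(utils::packageVersion("sipheno")),
    timestamp = format(Sys.time(), tz = "UTC"))
  jsonlite::write_json(manifest, file.path(output_dir, "manifest.json"),
                       auto_unbox = TRUE)
  invisible(list(entries = sel$entries, attrition = sel$attrition,
                 profiles = profiles, classifications = cls$classifications,
                 counts = cls$counts, calibration = cal))
}
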