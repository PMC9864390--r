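#' Apply eligibility criteria and derive index dates
#'
#' Eligibility (applied in order, each step counted in the attrition report):
#' (1) age at least 18 on the index date; (2) at least one consultation — any
#' dated diagnosis or prescription — inside the selection window; (3) at least
#' one lipid-lowering prescription inside the study period; (4) at least one
#' qualifying diagnosis (ASCVD, high CV risk or hypercholesterolemia) before
#' the end of the selection window. The index date is the latest statin
#' prescription in the study period, or failing that the latest non-statin
#' lipid-lowering prescription; the lookback starts `lookback_days` before the
#' index date, never before `study_start`.
#'
#' @param cohort An [emr_cohort()].
#' @param config A [study_config()].
#' @return List with `entries` (tibble: `patient_id`, `index_date`,
#'   `lookback_start`, `age_at_index`, logical `ascvd`, `high_cv_risk`,
#'   `hypercholesterolemia`) and `attrition` (tibble of per-step removals).
#' @export
select_cohort <- function(cohort, config = study_config()) {
  pats <- cohort$patients
  rx <- dplyr::filter(cohort$prescriptions,
                      .data$date >= config$study_start,
                      .data$date < config$study_end)

  llt <- dplyr::filter(rx, matches_prefix(.data$atc, config$atc_sets$llt))
  is_statin <- matches_prefix(llt$atc, config$atc_sets$statin)
  if (nrow(llt) == 0) {
    idx <- tibble::tibble(patient_id = character(),
                          index_date = as.Date(character()), has_llt = logical())
  } else {
    idx <- llt |>
      dplyr::mutate(statin = is_statin) |>
      dplyr::group_by(.data$patient_id) |>
      dplyr::summarise(
        index_date = if (any(.data$statin)) max(.data$date[.data$statin]) else max(.data$date),
        has_llt = TRUE, .groups = "drop")
  }

  df <- dplyr::left_join(pats, idx, by = "patient_id")
  df$has_llt[is.na(df$has_llt)] <- FALSE
  df$age_at_index <- as.integer(format(df$index_date, "%Y")) - df$birth_year

  consult_ids <- unique(c(
    cohort$diagnoses$patient_id[cohort$diagnoses$date >= config$selection_start &
                                  cohort$diagnoses$date < config$selection_end],
    cohort$prescriptions$patient_id[cohort$prescriptions$date >= config$selection_start &
                                      cohort$prescriptions$date < config$selection_end]))

  sub <- tag_subgroups(cohort, config)
  df <- dplyr::left_join(df, sub, by = "patient_id")
  for (s in c("ascvd", "high_cv_risk", "hypercholesterolemia")) {
    df[[s]][is.na(df[[s]])] <- FALSE
  }

  n0 <- nrow(df)
  keep_age <- is.na(df$age_at_index) | df$age_at_index >= 18L
  df <- df[keep_age, , drop = FALSE]
  n_age <- n0 - nrow(df)
  keep_consult <- df$patient_id %in% consult_ids
  df <- df[keep_consult, , drop = FALSE]
  n_consult <- sum(!keep_consult)
  keep_llt <- df$has_llt
  df <- df[keep_llt, , drop = FALSE]
  n_llt <- sum(!keep_llt)
  keep_diag <- df$ascvd | df$high_cv_risk | df$hypercholesterolemia
  df <- df[keep_diag, , drop = FALSE]
  n_diag <- sum(!keep_diag)

  entries <- tibble::tibble(
    patient_id = df$patient_id,
    index_date = df$index_date,
    lookback_start = pmax(config$study_start, df$index_date - config$lookback_days),
    age_at_index = df$age_at_index,
    ascvd = df$ascvd, high_cv_risk = df$high_cv_risk,
    hypercholesterolemia = df$hypercholesterolemia)

  attrition <- tibble::tibble(
    step = c("input", "age_lt_18", "no_consultation_in_selection",
             "no_llt_in_study", "no_qualifying_diagnosis", "eligible"),
    n_removed = c(0L, n_age, n_consult, n_llt, n_diag, 0L),
    n_remaining = c(n0, n0 - n_age, n0 - n_age - n_consult,
                    n0 - n_age - n_consult - n_llt,
                    nrow(entries), nrow(entries)))
  list(entries = entries, attrition = attrition)
}

#' Tag qualifying-diagnosis subgroups
#'
#' A patient carries a subgroup tag iff at least one diagnosis code matches
#' the configured ICD-10 prefix set at any time before the end of the
#' selection window ("during the selection period or in the past"). Tags are
#' not mutually exclusive.
#'
#' @param cohort An [emr_cohort()].
#' @param config A [study_config()].
#' @param phenotypes Subgroup names to tag; each must be a key of
#'   `config$code_sets`.
#' @return Tibble `patient_id` plus one logical column per phenotype.
#' @export
tag_subgroups <- function(cohort, config = study_config(),
                          phenotypes = c("ascvd", "high_cv_risk",
                                         "hypercholesterolemia")) {
  unknown <- setdiff(phenotypes, names(config$code_sets))
  assert_that(length(unknown) == 0,
              paste0("unknown phenotype(s) in config: ",
                     paste(unknown, collapse = ", ")))
  dg <- dplyr::filter(cohort$diagnoses, .data$date < config$selection_end)
  out <- tibble::tibble(patient_id = unique(cohort$patients$patient_id))
  for (ph in phenotypes) {
    ids <- unique(dg$patient_id[matches_prefix(dg$icd10, config$code_sets[[ph]])])
    out[[ph]] <- out$patient_id %in% ids
  }
  out
}
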