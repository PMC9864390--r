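#' Build a patient's statin exposure history
#'
#' Restricts the prescription stream to statin scripts (ATC C10AA and the
#' statin component of fixed-dose combinations) dated inside
#' `[lookback_start, study_end)`, annotated with the intensity class of each
#' script. An empty exposure is valid (non-statin-only patients).
#'
#' @param cohort An [emr_cohort()] (or a prescriptions tibble).
#' @param entry One row of the entries tibble from [select_cohort()].
#' @param config A [study_config()].
#' @return Exposure tibble: `patient_id`, `date`, `molecule`, `dose_mg`,
#'   `intensity` (ordered low < moderate < high), `days_supplied`.
#' @export
build_exposure <- function(cohort, entry, config = study_config()) {
  rx <- if (inherits(cohort, "emr_cohort")) cohort$prescriptions else cohort
  rx <- dplyr::filter(rx, .data$patient_id == entry$patient_id,
                      .data$date >= entry$lookback_start,
                      .data$date < config$study_end,
                      matches_prefix(.data$atc, config$atc_sets$statin))
  rx <- dplyr::arrange(rx, .data$date, .data$molecule)
  tibble::tibble(
    patient_id = rx$patient_id, date = rx$date, molecule = rx$molecule,
    dose_mg = rx$dose_mg,
    intensity = statin_intensity(rx$molecule, rx$dose_mg, config$intensity_map),
    days_supplied = rx$days_supplied)
}

#' Detect statin down-titration
#'
#' A same-molecule down-titration is a consecutive pair of scripts sharing the
#' molecule with a strictly lower dose; a different-molecule down-titration is
#' a consecutive pair changing molecule with a strictly lower intensity class.
#' Pairs on the same calendar day (concurrent prescribing) are not
#' transitions.
#'
#' @param exposure Output of [build_exposure()].
#' @return List `same_molecule`, `diff_molecule` (logicals) and `first_event`
#'   (one-row tibble `from_molecule`, `from_dose`, `to_molecule`, `to_dose`,
#'   `date`, or NULL when no event).
#' @export
detect_down_titration <- function(exposure) {
  p <- consecutive_pairs(exposure)
  list(same_molecule = any(p$dt_same), diff_molecule = any(p$dt_diff),
       first_event = first_pair(p, p$dt_same | p$dt_diff))
}

#' Detect statin switch and multi-statin use
#'
#' A switch is a consecutive pair changing molecule at an unchanged intensity
#' class (neither up- nor down-titration). Multi-statin use is molecule
#' plurality beyond one clean transition: three or more distinct molecules, a
#' return to a previously used molecule, or two distinct molecules prescribed
#' on the same day.
#'
#' @param exposure Output of [build_exposure()].
#' @return List `switch`, `multi_statin`, `first_event` (as in
#'   [detect_down_titration()]).
#' @export
detect_switch <- function(exposure) {
  p <- consecutive_pairs(exposure)
  n_runs <- if (nrow(exposure) == 0) 0L else
    sum(exposure$molecule != dplyr::lag(exposure$molecule), na.rm = TRUE) + 1L
  n_mol <- dplyr::n_distinct(exposure$molecule)
  same_day_multi <- any(p$same_day & p$mol_change)
  multi <- n_mol >= 3L || (n_mol >= 2L && n_runs >= 3L) || same_day_multi
  list(switch = any(p$switch), multi_statin = multi,
       first_event = first_pair(p, p$switch))
}

#' Detect permanent and prior statin discontinuation
#'
#' Coverage of a script ends at `date + days_supplied` (default supply when
#' absent). Permanent discontinuation: the gap from the last script's coverage
#' end to the study end strictly exceeds `gap_days`. Prior discontinuation:
#' any internal gap between one script's coverage end and the next script
#' strictly exceeds `gap_days`.
#'
#' @param exposure Output of [build_exposure()].
#' @param config A [study_config()].
#' @return List `permanent`, `prior` (logicals; both FALSE for an empty
#'   exposure).
#' @export
detect_discontinuation <- function(exposure, config = study_config()) {
  if (nrow(exposure) == 0) return(list(permanent = FALSE, prior = FALSE))
  cov_end <- exposure$date + dplyr::coalesce(as.integer(exposure$days_supplied),
                                             config$days_supplied_default)
  terminal_gap <- as.numeric(config$study_end - max(cov_end))
  internal_gap <- as.numeric(exposure$date[-1] -
                               head(cummax(as.numeric(cov_end)), -1))
  list(permanent = terminal_gap > config$gap_days,
       prior = any(internal_gap > config$gap_days))
}

#' Detect intermittent dosing
#'
#' Operationalised as a medication-possession ratio (total days supplied over
#' the covered span) strictly below `mpr_threshold`, for histories of at least
#' three scripts that are not permanently discontinued.
#'
#' @param exposure Output of [build_exposure()].
#' @param config A [study_config()].
#' @return Logical.
#' @export
detect_intermittent <- function(exposure, config = study_config()) {
  if (nrow(exposure) < 3) return(FALSE)
  if (detect_discontinuation(exposure, config)$permanent) return(FALSE)
  supply <- dplyr::coalesce(as.integer(exposure$days_supplied),
                            config$days_supplied_default)
  span <- as.numeric(max(exposure$date) - min(exposure$date))
  mpr <- sum(supply) / (span + supply[which.max(exposure$date)])
  mpr < config$mpr_threshold
}

#' Detect exclusive low-dose statin use
#'
#' TRUE iff every script's dose is at or below the molecule's lowest marketed
#' daily dose. Scripts with an unrecorded dose never qualify as low.
#'
#' @param exposure Output of [build_exposure()] (non-empty).
#' @param lowest_dose Named numeric vector, see [default_lowest_dose()].
#' @return Logical.
#' @export
detect_low_dose <- function(exposure, lowest_dose = default_lowest_dose()) {
  assert_that(nrow(exposure) > 0, "low-dose detection needs a non-empty exposure")
  unknown <- setdiff(unique(exposure$molecule), names(lowest_dose))
  assert_that(length(unknown) == 0,
              paste0("no lowest marketed dose configured for: ",
                     paste(unknown, collapse = ", ")))
  all(!is.na(exposure$dose_mg) &
        exposure$dose_mg <= lowest_dose[exposure$molecule])
}

#' Detect statin-associated muscle symptoms (SAMS)
#'
#' TRUE iff at least one diagnosis inside `[lookback_start, study_end)`
#' matches the configured SAMS ICD-10 prefixes.
#'
#' @param cohort An [emr_cohort()] (or a diagnoses tibble).
#' @param entry One row of the entries tibble from [select_cohort()].
#' @param config A [study_config()].
#' @return Logical.
#' @export
detect_sams <- function(cohort, entry, config = study_config()) {
  dg <- if (inherits(cohort, "emr_cohort")) cohort$diagnoses else cohort
  dg <- dplyr::filter(dg, .data$patient_id == entry$patient_id,
                      .data$date >= entry$lookback_start,
                      .data$date < config$study_end)
  any(matches_prefix(dg$icd10, config$code_sets$sams))
}

# Consecutive-pair transition flags for one exposure (sorted by date).
consecutive_pairs <- function(exposure) {
  if (nrow(exposure) < 2) {
    return(tibble::tibble(from_molecule = character(), from_dose = numeric(),
                          to_molecule = character(), to_dose = numeric(),
                          date = as.Date(character()), same_day = logical(),
                          mol_change = logical(), dt_same = logical(),
                          dt_diff = logical(), switch = logical()))
  }
  cur <- exposure[-1, ]
  prev <- exposure[-nrow(exposure), ]
  same_day <- cur$date == prev$date
  mol_change <- cur$molecule != prev$molecule
  int_cur <- as.integer(cur$intensity)
  int_prev <- as.integer(prev$intensity)
  tibble::tibble(
    from_molecule = prev$molecule, from_dose = prev$dose_mg,
    to_molecule = cur$molecule, to_dose = cur$dose_mg,
    date = cur$date, same_day = same_day, mol_change = mol_change,
    dt_same = !same_day & !mol_change &
      !is.na(cur$dose_mg) & !is.na(prev$dose_mg) & cur$dose_mg < prev$dose_mg,
    dt_diff = !same_day & mol_change &
      !is.na(int_cur) & !is.na(int_prev) & int_cur < int_prev,
    switch = !same_day & mol_change &
      !is.na(int_cur) & !is.na(int_prev) & int_cur == int_prev)
}

first_pair <- function(pairs, flag) {
  i <- which(flag)
  if (!length(i)) return(NULL)
  pairs[i[1], c("from_molecule", "from_dose", "to_molecule", "to_dose", "date")]
}

# Per-patient event flags from the annotated statin rows (sorted by patient,
# date, molecule). Fully vectorised: lags are taken over the whole table and
# masked at patient boundaries, per-patient aggregates use rowsum()/tabulate()
# on the run index, avoiding per-group R evaluation.
profile_statin_rows <- function(rx, config) {
  empty <- tibble::tibble(
    patient_id = character(), n_scripts = integer(),
    down_titration_same = logical(), down_titration_diff = logical(),
    switch = logical(), multi_statin = logical(),
    prior_discontinuation = logical(), terminal_gap = numeric(),
    mpr = numeric(), low_dose = logical(), low_intensity_only = logical(),
    dt_from_molecule = character(), dt_from_dose = numeric(),
    dt_to_molecule = character(), dt_to_dose = numeric(),
    sw_from_molecule = character(), sw_from_dose = numeric(),
    sw_to_molecule = character(), sw_to_dose = numeric())
  n <- nrow(rx)
  if (n == 0) return(empty)

  new <- c(TRUE, rx$patient_id[-1] != rx$patient_id[-n])
  gi <- cumsum(new)
  ng <- gi[n]
  size <- tabulate(gi, ng)
  last <- cumsum(size)
  shift <- function(x) x[c(NA, seq_len(n - 1L))]

  prev_mol <- shift(rx$molecule); prev_mol[new] <- NA
  prev_dose <- shift(rx$dose_mg); prev_dose[new] <- NA
  prev_int <- shift(rx$intensity_i); prev_int[new] <- NA
  prev_date <- shift(rx$date); prev_date[new] <- NA
  # running max of coverage end within each patient: add a per-patient offset
  # larger than the value range so a global cummax never crosses patients
  covn <- as.numeric(rx$cov_end)
  offset <- gi * (max(covn) - min(covn) + 1)
  run_max_cov <- cummax(covn + offset) - offset
  prev_cov <- shift(run_max_cov); prev_cov[new] <- NA

  same_day <- !new & rx$date == prev_date
  mol_change <- !new & rx$molecule != prev_mol
  dt_same <- !new & !same_day & !mol_change &
    !is.na(rx$dose_mg) & !is.na(prev_dose) & rx$dose_mg < prev_dose
  dt_diff <- !new & !same_day & mol_change &
    !is.na(rx$intensity_i) & !is.na(prev_int) & rx$intensity_i < prev_int
  sw <- !new & !same_day & mol_change &
    !is.na(rx$intensity_i) & !is.na(prev_int) & rx$intensity_i == prev_int
  internal_gap <- !new & as.numeric(rx$date) - prev_cov > config$gap_days
  supply <- as.numeric(rx$cov_end - rx$date)
  dt_flag <- dt_same | dt_diff

  grp_any <- function(flag) as.vector(rowsum(as.integer(flag), gi,
                                             reorder = FALSE)) > 0
  grp_sum <- function(x) as.vector(rowsum(x, gi, reorder = FALSE))

  mol_id <- match(rx$molecule, unique(rx$molecule))
  n_mol <- grp_sum(as.integer(!duplicated(gi * (max(mol_id) + 1L) + mol_id)))
  n_runs <- grp_sum(as.integer(mol_change)) + 1L

  min_date <- rx$date[new]
  max_date <- rx$date[last]
  # supply of the first script dated on the patient's last prescription day
  is_max <- rx$date == rep(max_date, size)
  w_max <- which(is_max)
  supply_last <- supply[w_max[!duplicated(gi[w_max])]]

  first_event <- function(flag) {
    w <- which(flag)
    w[!duplicated(gi[w])]
  }
  fill_first <- function(rows, values) {
    out <- values[NA_integer_][rep(1L, ng)]
    out[gi[rows]] <- values[rows]
    out
  }
  dt_rows <- first_event(dt_flag)
  sw_rows <- first_event(sw)

  tibble::tibble(
    patient_id = rx$patient_id[new],
    n_scripts = size,
    down_titration_same = grp_any(dt_same),
    down_titration_diff = grp_any(dt_diff),
    switch = grp_any(sw),
    multi_statin = n_mol >= 3L | (n_mol >= 2L & n_runs >= 3L) |
      grp_any(same_day & mol_change),
    prior_discontinuation = grp_any(internal_gap),
    terminal_gap = as.numeric(config$study_end) - run_max_cov[last],
    mpr = grp_sum(supply) /
      (as.numeric(max_date - min_date) + supply_last),
    low_dose = !grp_any(!rx$low),
    low_intensity_only = !grp_any(is.na(rx$intensity_i) | rx$intensity_i != 1L),
    dt_from_molecule = fill_first(dt_rows, prev_mol),
    dt_from_dose = fill_first(dt_rows, prev_dose),
    dt_to_molecule = fill_first(dt_rows, rx$molecule),
    dt_to_dose = fill_first(dt_rows, rx$dose_mg),
    sw_from_molecule = fill_first(sw_rows, prev_mol),
    sw_from_dose = fill_first(sw_rows, prev_dose),
    sw_to_molecule = fill_first(sw_rows, rx$molecule),
    sw_to_dose = fill_first(sw_rows, rx$dose_mg))
}

#' Compute SI event profiles for a whole cohort
#'
#' Runs every event detector over each patient's lookback window and collects
#' the per-patient flags that feed the rule engine, together with the first
#' down-titration and first switch transitions used by the reporting module.
#'
#' @param cohort An [emr_cohort()].
#' @param entries Entries tibble from [select_cohort()].
#' @param config A [study_config()].
#' @return Tibble with one row per entry: the event flags
#'   (`down_titration_same`, `down_titration_diff`, `switch`, `multi_statin`,
#'   `permanent_discontinuation`, `prior_discontinuation`, `intermittent`,
#'   `low_dose`, `low_intensity_only`, `sams`, `documented_si`), statin status
#'   (`has_statin_history`, `active_statin`) and first-event columns
#'   (`dt_from_molecule`, `dt_from_dose`, `dt_to_molecule`, `dt_to_dose`,
#'   `sw_from_molecule`, `sw_from_dose`, `sw_to_molecule`, `sw_to_dose`).
#' @export
build_event_profiles <- function(cohort, entries, config = study_config()) {
  rx <- dplyr::inner_join(cohort$prescriptions,
                          entries[c("patient_id", "lookback_start")],
                          by = "patient_id")
  rx <- dplyr::filter(rx, .data$date >= .data$lookback_start,
                      .data$date < config$study_end,
                      matches_prefix(.data$atc, config$atc_sets$statin))
  rx <- dplyr::arrange(rx, .data$patient_id, .data$date, .data$molecule)
  rx$intensity_i <- as.integer(statin_intensity(rx$molecule, rx$dose_mg,
                                                config$intensity_map))
  rx$cov_end <- rx$date + dplyr::coalesce(as.integer(rx$days_supplied),
                                          config$days_supplied_default)
  rx$low <- !is.na(rx$dose_mg) & rx$molecule %in% names(config$lowest_dose) &
    rx$dose_mg <= config$lowest_dose[rx$molecule]

  prof <- profile_statin_rows(rx, config)
  prof$permanent_discontinuation <- prof$terminal_gap > config$gap_days
  prof$intermittent <- prof$n_scripts >= 3L & !prof$permanent_discontinuation &
    prof$mpr < config$mpr_threshold
  prof$terminal_gap <- NULL
  prof$mpr <- NULL

  # SAMS flags from diagnoses within the lookback window
  dg <- dplyr::inner_join(cohort$diagnoses,
                          entries[c("patient_id", "lookback_start")],
                          by = "patient_id")
  dg <- dplyr::filter(dg, .data$date >= .data$lookback_start,
                      .data$date < config$study_end)
  sams_ids <- unique(dg$patient_id[matches_prefix(dg$icd10, config$code_sets$sams)])

  out <- dplyr::left_join(entries["patient_id"], prof, by = "patient_id")
  out <- dplyr::left_join(
    out, cohort$patients[c("patient_id", "documented_si_note")], by = "patient_id")
  flags <- c("down_titration_same", "down_titration_diff", "switch",
             "multi_statin", "prior_discontinuation",
             "permanent_discontinuation", "intermittent", "low_dose",
             "low_intensity_only")
  for (f in flags) out[[f]][is.na(out[[f]])] <- FALSE
  out$n_scripts[is.na(out$n_scripts)] <- 0L
  out$sams <- out$patient_id %in% sams_ids
  out$documented_si <- out$documented_si_note %in% TRUE
  out$documented_si_note <- NULL
  out$has_statin_history <- out$n_scripts > 0L
  out$active_statin <- out$has_statin_history & !out$permanent_discontinuation
  out
}
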