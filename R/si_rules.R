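#' Classify one patient's event profile into the five-way SI label
#'
#' Implements the rule table mapping event profiles to
#' `{tolerant, absolute_high, absolute_low, partial_high, partial_low}`.
#' Clauses are evaluated in fixed precedence order — stronger evidence first —
#' and the first match wins:
#'
#' * **AH1** (absolute, high confidence): ASCVD / high-CV-risk patient with no
#'   statin history, i.e. on non-statin lipid-lowering therapy only.
#' * **AH2**: long-term (permanent) discontinuation AND at least one sign
#'   event (down-titration, low-dose use, multi-statin use, SAMS, intermittent
#'   dosing, documented intolerance, prior discontinuation).
#' * **PH** (partial, high): actively on statins (no terminal gap) AND at
#'   least one sign from the same set.
#' * **AL** (absolute, low): permanent discontinuation without any sign.
#' * **PL1** (partial, low): ASCVD / high-CV-risk patient exclusively on
#'   low-intensity statins without any sign.
#' * **PL2**: no intermittent dosing and no discontinuation of the latest
#'   statins, with a down-titration or switch sign.
#'
#' A bare switch is deliberately absent from the AH2/PH sign set (the
#' high-confidence rows enumerate their signs without it); it contributes only
#' through PL2.
#'
#' @param profile One-row tibble (or list) of event flags as produced by
#'   [build_event_profiles()].
#' @param subgroups Character vector of subgroup tags (subset of `ascvd`,
#'   `high_cv_risk`, `hypercholesterolemia`).
#' @param has_statin_history Any statin script in the lookback window.
#' @param active_statin On statins with no terminal gap longer than
#'   `gap_days`; mutually exclusive with permanent discontinuation.
#' @return List `label`, `fired_rule` (`"none"` for tolerant), `sign_events`
#'   (character vector of contributing flags).
#' @export
classify_si <- function(profile, subgroups, has_statin_history, active_statin) {
  assert_that(!(isTRUE(profile$permanent_discontinuation) && isTRUE(active_statin)),
              "permanent discontinuation and active statin use are contradictory")
  cv <- any(c("ascvd", "high_cv_risk") %in% subgroups)
  sign_set <- c("down_titration_same", "down_titration_diff", "low_dose",
                "multi_statin", "sams", "intermittent", "documented_si",
                "prior_discontinuation")
  signs_on <- sign_set[vapply(sign_set, function(f) isTRUE(profile[[f]]), logical(1))]
  al_excl <- c("down_titration_same", "down_titration_diff", "switch",
               "low_dose", "sams", "intermittent", "documented_si")
  pl1_excl <- c("prior_discontinuation", "down_titration_same",
                "down_titration_diff", "switch", "sams", "intermittent",
                "documented_si")
  on <- function(f) isTRUE(profile[[f]])
  none_of <- function(fs) !any(vapply(fs, on, logical(1)))

  if (cv && !has_statin_history) {
    return(list(label = "absolute_high", fired_rule = "AH1",
                sign_events = character()))
  }
  if (on("permanent_discontinuation") && length(signs_on) > 0) {
    return(list(label = "absolute_high", fired_rule = "AH2",
                sign_events = signs_on))
  }
  if (isTRUE(active_statin) && length(signs_on) > 0) {
    return(list(label = "partial_high", fired_rule = "PH", sign_events = signs_on))
  }
  if (on("permanent_discontinuation") && none_of(al_excl)) {
    return(list(label = "absolute_low", fired_rule = "AL",
                sign_events = character()))
  }
  if (isTRUE(active_statin) && cv && on("low_intensity_only") && none_of(pl1_excl)) {
    return(list(label = "partial_low", fired_rule = "PL1",
                sign_events = "low_intensity_only"))
  }
  if (!on("intermittent") && !on("permanent_discontinuation") &&
      (on("down_titration_same") || on("down_titration_diff") || on("switch"))) {
    pl2_signs <- c("down_titration_same", "down_titration_diff", "switch")
    return(list(label = "partial_low", fired_rule = "PL2",
                sign_events = pl2_signs[vapply(pl2_signs, on, logical(1))]))
  }
  list(label = "tolerant", fired_rule = "none", sign_events = character())
}

#' Classify a whole cohort
#'
#' Vectorised application of [classify_si()] to the profile table, plus a
#' per-label count table. Patients with no statin history and no ASCVD /
#' high-CV-risk tag cannot be placed by the rule table and fall through to
#' tolerant; they are flagged in the `unclassifiable` diagnostic column.
#'
#' @param entries Entries tibble from [select_cohort()].
#' @param profiles Profile tibble from [build_event_profiles()].
#' @return List with `classifications` (tibble `patient_id`, `label`,
#'   `fired_rule`, `sign_events`, `unclassifiable`) and `counts` (tibble
#'   `label`, `n` over the five labels).
#' @export
classify_cohort <- function(entries, profiles) {
  assert_that(nrow(entries) == nrow(profiles) &&
                all(entries$patient_id == profiles$patient_id),
              "entries and profiles must align one-to-one")
  df <- dplyr::left_join(
    profiles,
    entries[c("patient_id", "ascvd", "high_cv_risk")], by = "patient_id")
  assert_that(!any(df$permanent_discontinuation & df$active_statin),
              "permanent discontinuation and active statin use are contradictory")

  cv <- df$ascvd | df$high_cv_risk
  sign_set <- c("down_titration_same", "down_titration_diff", "low_dose",
                "multi_statin", "sams", "intermittent", "documented_si",
                "prior_discontinuation")
  sign_mat <- as.matrix(df[sign_set])
  any_sign <- rowSums(sign_mat) > 0
  al_ok <- !(df$down_titration_same | df$down_titration_diff | df$switch |
               df$low_dose | df$sams | df$intermittent | df$documented_si)
  pl1_ok <- !(df$prior_discontinuation | df$down_titration_same |
                df$down_titration_diff | df$switch | df$sams |
                df$intermittent | df$documented_si)

  rule <- rep("none", nrow(df))
  hit <- function(cond, id) { sel <- rule == "none" & cond; rule[sel] <<- id }
  hit(cv & !df$has_statin_history, "AH1")
  hit(df$permanent_discontinuation & any_sign, "AH2")
  hit(df$active_statin & any_sign, "PH")
  hit(df$permanent_discontinuation & al_ok, "AL")
  hit(df$active_statin & cv & df$low_intensity_only & pl1_ok, "PL1")
  hit(!df$intermittent & !df$permanent_discontinuation &
        (df$down_titration_same | df$down_titration_diff | df$switch), "PL2")

  label <- c(AH1 = "absolute_high", AH2 = "absolute_high", PH = "partial_high",
             AL = "absolute_low", PL1 = "partial_low", PL2 = "partial_low",
             none = "tolerant")[rule]
  signs <- character(nrow(df))
  contributing <- rule %in% c("AH2", "PH")
  if (any(contributing)) {
    signs[contributing] <- apply(sign_mat[contributing, , drop = FALSE], 1,
                                 function(r) paste(sign_set[r > 0], collapse = ";"))
  }
  signs[rule == "PL1"] <- "low_intensity_only"
  pl2 <- rule == "PL2"
  if (any(pl2)) {
    m <- as.matrix(df[pl2, c("down_titration_same", "down_titration_diff",
                             "switch")])
    signs[pl2] <- apply(m, 1, function(r)
      paste(colnames(m)[r > 0], collapse = ";"))
  }

  classifications <- tibble::tibble(
    patient_id = df$patient_id,
    label = factor(unname(label), levels = si_labels()),
    fired_rule = unname(rule),
    sign_events = signs,
    unclassifiable = !df$has_statin_history & !cv)
  counts <- dplyr::count(classifications, .data$label, .drop = FALSE,
                         name = "n")
  list(classifications = classifications, counts = counts)
}
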