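test_that("AH1: CV patient on non-statin lipid-lowering therapy only", {
  out <- classify_si(base_profile(), subgroups = "ascvd",
                     has_statin_history = FALSE, active_statin = FALSE)
  expect_equal(out$label, "absolute_high")
  expect_equal(out$fired_rule, "AH1")
  # same history without the CV tag is not classifiable as AH1
  out2 <- classify_si(base_profile(), subgroups = "hypercholesterolemia",
                      has_statin_history = FALSE, active_statin = FALSE)
  expect_equal(out2$label, "tolerant")
})

test_that("AH2: permanent discontinuation plus any sign event", {
  for (sign in c("down_titration_same", "down_titration_diff", "low_dose",
                 "multi_statin", "sams", "intermittent", "documented_si",
                 "prior_discontinuation")) {
    args <- stats::setNames(list(TRUE, TRUE),
                            c("permanent_discontinuation", sign))
    out <- classify_si(do.call(base_profile, args),
                       subgroups = "hypercholesterolemia",
                       has_statin_history = TRUE, active_statin = FALSE)
    expect_equal(out$label, "absolute_high")
    expect_equal(out$fired_rule, "AH2")
    expect_equal(out$sign_events, sign)
  }
})

test_that("a bare switch is not an AH2/PH sign", {
  # discontinued with only a switch: falls through AH2 to AL's exclusion,
  # which does include switch, so the patient is tolerant, not absolute_low
  out <- classify_si(base_profile(permanent_discontinuation = TRUE, switch = TRUE),
                     subgroups = "hypercholesterolemia",
                     has_statin_history = TRUE, active_statin = FALSE)
  expect_equal(out$fired_rule, "none")
  # active with only a switch: not PH - lands in PL2
  out2 <- classify_si(base_profile(switch = TRUE),
                      subgroups = "hypercholesterolemia",
                      has_statin_history = TRUE, active_statin = TRUE)
  expect_equal(out2$label, "partial_low")
  expect_equal(out2$fired_rule, "PL2")
  expect_equal(out2$sign_events, "switch")
})

test_that("PH: active statin use plus a sign event", {
  out <- classify_si(base_profile(multi_statin = TRUE),
                     subgroups = "hypercholesterolemia",
                     has_statin_history = TRUE, active_statin = TRUE)
  expect_equal(out$label, "partial_high")
  expect_equal(out$fired_rule, "PH")
})

test_that("AL: permanent discontinuation without any sign", {
  out <- classify_si(base_profile(permanent_discontinuation = TRUE),
                     subgroups = "hypercholesterolemia",
                     has_statin_history = TRUE, active_statin = FALSE)
  expect_equal(out$label, "absolute_low")
  expect_equal(out$fired_rule, "AL")
  expect_equal(out$sign_events, character())
})

test_that("PL1: CV patient exclusively on low-intensity statins, no signs", {
  out <- classify_si(base_profile(low_intensity_only = TRUE),
                     subgroups = "ascvd",
                     has_statin_history = TRUE, active_statin = TRUE)
  expect_equal(out$label, "partial_low")
  expect_equal(out$fired_rule, "PL1")
  # hypercholesterolemia alone does not qualify for PL1
  out2 <- classify_si(base_profile(low_intensity_only = TRUE),
                      subgroups = "hypercholesterolemia",
                      has_statin_history = TRUE, active_statin = TRUE)
  expect_equal(out2$label, "tolerant")
  # a sign event promotes the patient to PH before PL1 is reached
  out3 <- classify_si(base_profile(low_intensity_only = TRUE, sams = TRUE),
                      subgroups = "ascvd",
                      has_statin_history = TRUE, active_statin = TRUE)
  expect_equal(out3$fired_rule, "PH")
})

test_that("PL2 requires no intermittent dosing and no permanent discontinuation", {
  ok <- classify_si(base_profile(down_titration_same = TRUE),
                    subgroups = "hypercholesterolemia",
                    has_statin_history = TRUE, active_statin = TRUE)
  expect_equal(ok$fired_rule, "PH")   # down-titration is a PH sign when active
  # simulate a past down-titration with neither active use nor permanent stop
  # (e.g. statins stopped recently, inside the gap window)
  mid <- classify_si(base_profile(switch = TRUE),
                     subgroups = "hypercholesterolemia",
                     has_statin_history = TRUE, active_statin = FALSE)
  expect_equal(mid$fired_rule, "PL2")
})

test_that("clause order: earlier rules shadow later ones", {
  # permanent + sign + switch: AH2, never AL or PL2
  out <- classify_si(base_profile(permanent_discontinuation = TRUE,
                                  sams = TRUE, switch = TRUE),
                     subgroups = "ascvd",
                     has_statin_history = TRUE, active_statin = FALSE)
  expect_equal(out$fired_rule, "AH2")
  # AH1 shadows everything for non-statin CV patients
  out2 <- classify_si(base_profile(), subgroups = c("ascvd", "hypercholesterolemia"),
                      has_statin_history = FALSE, active_statin = FALSE)
  expect_equal(out2$fired_rule, "AH1")
})

test_that("tolerant: active statin use with no signs", {
  out <- classify_si(base_profile(), subgroups = "hypercholesterolemia",
                     has_statin_history = TRUE, active_statin = TRUE)
  expect_equal(out$label, "tolerant")
  expect_equal(out$fired_rule, "none")
})

test_that("contradictory inputs are rejected", {
  expect_error(
    classify_si(base_profile(permanent_discontinuation = TRUE),
                subgroups = "ascvd",
                has_statin_history = TRUE, active_statin = TRUE),
    "contradictory")
})

test_that("classify_cohort matches row-wise classify_si on a random cohort", {
  g <- generate_cohort(scenario_config(400, seed = 17))
  sel <- select_cohort(g$cohort)
  prof <- build_event_profiles(g$cohort, sel$entries)
  out <- classify_cohort(sel$entries, prof)
  expect_equal(nrow(out$classifications), nrow(sel$entries))
  for (i in seq_len(nrow(prof))) {
    e <- sel$entries[i, ]
    subs <- c("ascvd", "high_cv_risk", "hypercholesterolemia")[
      c(e$ascvd, e$high_cv_risk, e$hypercholesterolemia)]
    ref <- classify_si(prof[i, ], subs, prof$has_statin_history[i],
                       prof$active_statin[i])
    expect_equal(as.character(out$classifications$label[i]), ref$label)
    expect_equal(out$classifications$fired_rule[i], ref$fired_rule)
    expect_equal(out$classifications$sign_events[i],
                 paste(ref$sign_events, collapse = ";"))
  }
})

test_that("classification is a partition: counts cover all labels and sum to n", {
  g <- generate_cohort(scenario_config(500, seed = 23))
  sel <- select_cohort(g$cohort)
  out <- classify_cohort(sel$entries, build_event_profiles(g$cohort, sel$entries))
  expect_equal(sort(as.character(out$counts$label)),
               sort(c("tolerant", "absolute_high", "absolute_low",
                      "partial_high", "partial_low")))
  expect_equal(sum(out$counts$n), nrow(sel$entries))
  expect_false(any(is.na(out$classifications$label)))
})

test_that("patients with no statin history and no CV tag are flagged unclassifiable", {
  co <- mk_cohort(
    diagnoses = tibble::tibble(patient_id = "P1",
                               date = as.Date("2019-06-01"), icd10 = "E78.0"),
    prescriptions = mk_rx("P1", "2019-06-01", "ezetimibe", NA))
  sel <- select_cohort(co)
  out <- classify_cohort(sel$entries, build_event_profiles(co, sel$entries))
  expect_equal(as.character(out$classifications$label), "tolerant")
  expect_true(out$classifications$unclassifiable)
})
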