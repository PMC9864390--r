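cfg <- study_config()

test_that("build_exposure keeps only statins inside the lookback window", {
  co <- mk_cohort(prescriptions = dplyr::bind_rows(
    mk_rx("P1", "2017-06-01", "simvastatin", 20),   # before lookback
    mk_rx("P1", "2019-05-01", "simvastatin", 20),
    mk_rx("P1", "2019-06-01", "ezetimibe", NA)))    # not a statin
  entry <- tibble::tibble(patient_id = "P1",
                          lookback_start = as.Date("2018-01-01"))
  ex <- build_exposure(co, entry, cfg)
  expect_equal(nrow(ex), 1L)
  expect_equal(ex$molecule, "simvastatin")
  expect_equal(as.character(ex$intensity), "moderate")
})

test_that("down-titration: same-molecule dose drop and cross-molecule intensity drop", {
  ex <- mk_exposure(c("2019-01-01", "2019-03-01"), "atorvastatin", c(40, 20))
  dt <- detect_down_titration(ex)
  expect_true(dt$same_molecule)
  expect_false(dt$diff_molecule)
  expect_equal(dt$first_event$from_dose, 40)
  expect_equal(dt$first_event$to_dose, 20)

  # atorvastatin 40 (high) -> simvastatin 20 (moderate)
  ex2 <- mk_exposure(c("2019-01-01", "2019-03-01"),
                     c("atorvastatin", "simvastatin"), c(40, 20))
  dt2 <- detect_down_titration(ex2)
  expect_false(dt2$same_molecule)
  expect_true(dt2$diff_molecule)
  expect_false(detect_switch(ex2)$switch)
})

test_that("up-titration is not a down-titration and not a switch", {
  ex <- mk_exposure(c("2019-01-01", "2019-03-01"), "simvastatin", c(20, 40))
  expect_false(detect_down_titration(ex)$same_molecule)
  expect_false(detect_switch(ex)$switch)
  # moderate -> high across molecules
  ex2 <- mk_exposure(c("2019-01-01", "2019-03-01"),
                     c("simvastatin", "atorvastatin"), c(20, 40))
  expect_false(detect_down_titration(ex2)$diff_molecule)
  expect_false(detect_switch(ex2)$switch)
})

test_that("intensity-preserving molecule change is a switch, not a down-titration", {
  ex <- mk_exposure(c("2019-01-01", "2019-03-01"),
                    c("simvastatin", "atorvastatin"), c(20, 20))
  sw <- detect_switch(ex)
  expect_true(sw$switch)
  expect_false(sw$multi_statin)
  expect_false(detect_down_titration(ex)$same_molecule)
  expect_false(detect_down_titration(ex)$diff_molecule)
  expect_equal(sw$first_event$to_molecule, "atorvastatin")
})

test_that("same-day concurrent scripts are not transitions but flag multi-statin", {
  ex <- mk_exposure(c("2019-01-01", "2019-01-01"),
                    c("simvastatin", "atorvastatin"), c(20, 20))
  sw <- detect_switch(ex)
  expect_false(sw$switch)
  expect_true(sw$multi_statin)
  expect_false(detect_down_titration(ex)$same_molecule)
})

test_that("multi-statin use: three molecules, or a return to a prior molecule", {
  three <- mk_exposure(as.Date("2019-01-01") + c(0, 60, 120),
                       c("simvastatin", "atorvastatin", "rosuvastatin"),
                       c(20, 20, 10))
  expect_true(detect_switch(three)$multi_statin)
  back <- mk_exposure(as.Date("2019-01-01") + c(0, 60, 120),
                      c("simvastatin", "atorvastatin", "simvastatin"),
                      c(20, 10, 20))
  expect_true(detect_switch(back)$multi_statin)
  clean <- mk_exposure(as.Date("2019-01-01") + c(0, 60),
                       c("simvastatin", "atorvastatin"), c(20, 20))
  expect_false(detect_switch(clean)$multi_statin)
})

test_that("a terminal gap of exactly 180 days is not permanent discontinuation", {
  # coverage ends 2019-10-03; study end 2020-03-31 -> gap exactly 180
  ex <- mk_exposure("2019-09-03", "simvastatin", 20, days_supplied = 30)
  expect_false(detect_discontinuation(ex, cfg)$permanent)
  ex2 <- mk_exposure("2019-09-02", "simvastatin", 20, days_supplied = 30)
  expect_true(detect_discontinuation(ex2, cfg)$permanent)   # gap 181
})

test_that("an internal gap of exactly 180 days is not prior discontinuation", {
  # first coverage ends 2018-01-31; +180 days lands on 2018-07-30
  ex <- mk_exposure(c("2018-01-01", "2018-07-30"), "simvastatin", c(20, 20))
  expect_false(detect_discontinuation(ex, cfg)$prior)
  ex2 <- mk_exposure(c("2018-01-01", "2018-07-31"), "simvastatin", c(20, 20))
  expect_true(detect_discontinuation(ex2, cfg)$prior)
})

test_that("empty exposure yields no discontinuation", {
  ex <- mk_exposure(character(), character(), numeric())
  expect_equal(detect_discontinuation(ex, cfg),
               list(permanent = FALSE, prior = FALSE))
})

test_that("intermittent dosing requires >=3 scripts, no permanent stop, MPR < 0.5", {
  sparse <- mk_exposure(as.Date(c("2019-02-01", "2019-08-01", "2020-02-01")),
                        "simvastatin", 20)   # MPR = 90 / 395
  expect_true(detect_intermittent(sparse, cfg))
  dense <- mk_exposure(as.Date("2019-06-01") + (0:8) * 30, "simvastatin", 20)
  expect_false(detect_intermittent(dense, cfg))
  two <- mk_exposure(as.Date(c("2019-02-01", "2020-02-01")), "simvastatin", 20)
  expect_false(detect_intermittent(two, cfg))
  # same spacing but ending long before study end: permanently discontinued
  old <- mk_exposure(as.Date(c("2017-04-01", "2017-10-01", "2018-04-01")),
                     "simvastatin", 20)
  expect_false(detect_intermittent(old, cfg))
  expect_true(detect_discontinuation(old, cfg)$permanent)
})

test_that("an MPR of exactly 0.5 is not intermittent (strict inequality)", {
  # three 30-day scripts over a 150-day span: 90 / (150 + 30) = 0.5
  ex <- mk_exposure(as.Date("2019-10-01") + c(0, 75, 150), "simvastatin", 20)
  expect_false(detect_intermittent(ex, cfg))
  # one day wider: 90 / 181 < 0.5
  ex2 <- mk_exposure(as.Date("2019-10-01") + c(0, 75, 151), "simvastatin", 20)
  expect_true(detect_intermittent(ex2, cfg))
})

test_that("low-dose use means every script at or below the lowest marketed dose", {
  expect_true(detect_low_dose(mk_exposure(
    c("2019-05-01", "2019-06-01"), "simvastatin", c(10, 10))))
  expect_false(detect_low_dose(mk_exposure(
    c("2019-05-01", "2019-06-01"), "simvastatin", c(10, 20))))
  # pravastatin 20 is low intensity but above its lowest dose (10)
  expect_false(detect_low_dose(mk_exposure("2019-05-01", "pravastatin", 20)))
  # unrecorded dose never counts as low
  expect_false(detect_low_dose(mk_exposure("2019-05-01", "simvastatin", NA)))
  expect_error(detect_low_dose(mk_exposure(character(), character(), numeric())),
               "non-empty")
})

test_that("SAMS detection respects the lookback window", {
  co <- mk_cohort(diagnoses = tibble::tibble(
    patient_id = c("P1", "P1"),
    date = as.Date(c("2017-05-01", "2019-05-01")),
    icd10 = c("M79.1", "J06.9")))
  entry_late <- tibble::tibble(patient_id = "P1",
                               lookback_start = as.Date("2018-01-01"))
  expect_false(detect_sams(co, entry_late, cfg))
  entry_early <- tibble::tibble(patient_id = "P1",
                                lookback_start = as.Date("2017-03-01"))
  expect_true(detect_sams(co, entry_early, cfg))
})

test_that("cohort-level profiles agree with the single-patient detectors", {
  g <- generate_cohort(scenario_config(150, seed = 31))
  sel <- select_cohort(g$cohort)
  prof <- build_event_profiles(g$cohort, sel$entries)
  expect_equal(prof$patient_id, sel$entries$patient_id)
  for (i in seq_len(nrow(sel$entries))) {
    e <- sel$entries[i, ]
    ex <- build_exposure(g$cohort, e, cfg)
    p <- prof[i, ]
    dt <- detect_down_titration(ex)
    sw <- detect_switch(ex)
    dc <- detect_discontinuation(ex, cfg)
    expect_equal(p$down_titration_same, dt$same_molecule)
    expect_equal(p$down_titration_diff, dt$diff_molecule)
    expect_equal(p$switch, sw$switch)
    expect_equal(p$multi_statin, sw$multi_statin)
    expect_equal(p$permanent_discontinuation, dc$permanent)
    expect_equal(p$prior_discontinuation, dc$prior)
    expect_equal(p$intermittent, detect_intermittent(ex, cfg))
    if (nrow(ex) > 0) expect_equal(p$low_dose, detect_low_dose(ex, cfg$lowest_dose))
    expect_equal(p$sams, detect_sams(g$cohort, e, cfg))
    expect_equal(p$has_statin_history, nrow(ex) > 0)
    if (!is.null(dt$first_event)) {
      expect_equal(p$dt_from_molecule, dt$first_event$from_molecule)
      expect_equal(p$dt_to_dose, dt$first_event$to_dose)
    } else {
      expect_true(is.na(p$dt_from_molecule))
    }
  }
})

test_that("patients without statin scripts get an all-FALSE profile", {
  co <- mk_cohort(
    diagnoses = tibble::tibble(patient_id = "P1",
                               date = as.Date("2019-06-01"), icd10 = "I25.1"),
    prescriptions = mk_rx("P1", "2019-06-01", "ezetimibe", NA))
  sel <- select_cohort(co)
  prof <- build_event_profiles(co, sel$entries)
  expect_false(prof$has_statin_history)
  expect_false(prof$active_statin)
  expect_false(prof$permanent_discontinuation)
  expect_false(prof$low_dose)
  expect_equal(prof$n_scripts, 0L)
})
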