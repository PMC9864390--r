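#' Scenario configuration for the synthetic EMR generator
#'
#' Defines the planted phenotype mix and the statistical structure of the
#' simulated cohort: how often each of the five phenotype labels occurs, how
#' likely a low-confidence patient is to be truly intolerant, and how strongly
#' true intolerance elevates the stochastic "signal" features (rate ratios
#' relative to the tolerant baseline). Baselines follow the tolerant column of
#' published outpatient characteristics tables (myalgia ~1.9%, muscle
#' cramps/spasms ~2.2%, ezetimibe use ~9.6%, vitamin-D deficiency ~17%).
#'
#' @param n_patients Number of patients to simulate.
#' @param seed Integer seed; identical seeds give identical cohorts.
#' @param class_mix Named probabilities over `tolerant`, `absolute_high`,
#'   `absolute_low`, `partial_high`, `partial_low`; must sum to 1. Defaults to
#'   the rule-stage shares of a large German outpatient cohort
#'   (0.766/0.064/0.094/0.028/0.048).
#' @param latent_si_given_low_conf Probability that a low-confidence patient
#'   (absolute_low / partial_low) is truly intolerant (default 0.5). Truly
#'   intolerant patients draw the signal features at elevated rates but carry
#'   no deterministic sign events beyond their class-defining trajectory —
#'   they are exactly the population the calibration model must recover.
#' @param signal_effects Named rate ratios (true-SI vs tolerant) for the
#'   stochastic features. Defaults: myalgia 2.2, cramps 1.9, fibrate use 5.0,
#'   visit count 1.3, plus weaker gradients for ezetimibe use and comorbid
#'   risk factors.
#' @param baseline_rates Named per-patient probabilities of each stochastic
#'   event for tolerant patients; `visit_count` is a Poisson mean of extra
#'   consultation diagnoses. Setting all of these to zero switches stochastic
#'   co-occurrence off entirely (see [noiseless_scenario()]).
#' @param n_noise_features Count of pure-noise ICD-10 codes, each present in
#'   any patient with probability `noise_feature_rate`, independent of the
#'   phenotype (default 30).
#' @param noise_feature_rate Per-patient presence probability of each noise
#'   code (default 0.05).
#'
#' @return A `scenario_config` list.
#' @export
scenario_config <- function(n_patients,
                            seed = 1L,
                            class_mix = c(tolerant = 0.766, absolute_high = 0.064,
                                          absolute_low = 0.094, partial_high = 0.028,
                                          partial_low = 0.048),
                            latent_si_given_low_conf = 0.5,
                            signal_effects = c(myalgia = 2.2, cramps = 1.9,
                                               fibrate_use = 5.0, visit_count = 1.3,
                                               ezetimibe_use = 2.25,
                                               vitamin_d = 1.25, hypothyroidism = 1.1,
                                               obesity = 1.05, ckd = 1.1),
                            baseline_rates = c(myalgia = 0.019, cramps = 0.022,
                                               myositis = 0.0005, myopathy = 0.001,
                                               fibrate_use = 0.02, ezetimibe_use = 0.096,
                                               vitamin_d = 0.172, hypothyroidism = 0.088,
                                               obesity = 0.094, ckd = 0.046,
                                               documented_si = 0.002,
                                               visit_count = 8),
                            n_noise_features = 30L,
                            noise_feature_rate = 0.05) {
  assert_that(n_patients >= 1, "n_patients must be positive")
  labs <- si_labels()
  assert_that(all(labs %in% names(class_mix)),
              "class_mix must name all five phenotype labels")
  class_mix <- class_mix[labs]
  assert_that(abs(sum(class_mix) - 1) < 1e-9, "class_mix must sum to 1")
  assert_that(all(class_mix >= 0 & class_mix <= 1),
              "class_mix probabilities must lie in [0, 1]")
  assert_that(latent_si_given_low_conf >= 0 && latent_si_given_low_conf <= 1,
              "latent_si_given_low_conf must lie in [0, 1]")
  assert_that(all(signal_effects > 0), "rate ratios must be positive")
  structure(list(
    n_patients = as.integer(n_patients), seed = as.integer(seed),
    class_mix = class_mix,
    latent_si_given_low_conf = latent_si_given_low_conf,
    signal_effects = signal_effects, baseline_rates = baseline_rates,
    n_noise_features = as.integer(n_noise_features),
    noise_feature_rate = noise_feature_rate
  ), class = "scenario_config")
}

#' Noiseless scenario: planted trajectories only
#'
#' Convenience wrapper around [scenario_config()] with every stochastic event
#' rate set to zero and no noise features, so each patient carries exactly the
#' event signature of their planted class. On such cohorts the rule engine
#' recovers every planted label.
#'
#' @inheritParams scenario_config
#' @param ... Passed to [scenario_config()].
#' @return A `scenario_config`.
#' @export
noiseless_scenario <- function(n_patients, seed = 1L, ...) {
  base <- scenario_config(1)$baseline_rates
  scenario_config(n_patients, seed = seed,
                  baseline_rates = setNames(rep(0, length(base)), names(base)),
                  n_noise_features = 0L, ...)
}

si_labels <- function() {
  c("tolerant", "absolute_high", "absolute_low", "partial_high", "partial_low")
}

statin_atc_codes <- c(simvastatin = "C10AA01", lovastatin = "C10AA02",
                      pravastatin = "C10AA03", fluvastatin = "C10AA04",
                      atorvastatin = "C10AA05", rosuvastatin = "C10AA07",
                      pitavastatin = "C10AA08")
nonstatin_atc_codes <- c(ezetimibe = "C10AX09", fenofibrate = "C10AB05",
                         bezafibrate = "C10AB02")

rand_dates <- function(n, from, to) {
  from + floor(runif(n) * as.numeric(to - from))
}

# Expand a segments table (patient_id, molecule, dose_mg, n, start, interval)
# into dated prescription rows. Refill dates get +/-2 day jitter after the
# first script of each segment.
segments_to_scripts <- function(seg, days_supplied = 30L) {
  if (nrow(seg) == 0 || sum(seg$n) == 0) {
    return(tibble::tibble(patient_id = character(), date = as.Date(character()),
                          atc = character(), molecule = character(),
                          dose_mg = numeric(), days_supplied = integer()))
  }
  seg <- seg[seg$n > 0, , drop = FALSE]
  r <- rep(seq_len(nrow(seg)), seg$n)
  k <- sequence(seg$n)
  jit <- sample(-2:2, length(r), replace = TRUE) * (k > 1)
  mol <- seg$molecule[r]
  tibble::tibble(
    patient_id = seg$patient_id[r],
    date = seg$start[r] + (k - 1L) * seg$interval[r] + jit,
    atc = unname(c(statin_atc_codes, nonstatin_atc_codes)[mol]),
    molecule = mol,
    dose_mg = seg$dose_mg[r],
    days_supplied = rep(days_supplied, length(r))
  )
}

# Number of ~interval-day refills from `start` reaching `target_end`.
n_refills <- function(start, target_end, interval) {
  pmax(1L, as.integer(as.numeric(target_end - start) %/% interval) + 1L)
}

# Statin molecules and non-lowest moderate-or-higher doses used for patients
# who must NOT look low-dose or low-intensity.
sample_maintenance_statin <- function(n) {
  mol <- sample(c("simvastatin", "atorvastatin", "rosuvastatin", "pravastatin",
                  "fluvastatin"), n, replace = TRUE,
                prob = c(0.50, 0.37, 0.06, 0.05, 0.02))
  dose <- numeric(n)
  dose[mol == "simvastatin"] <- sample(c(20, 40), sum(mol == "simvastatin"), TRUE)
  dose[mol == "atorvastatin"] <- sample(c(20, 40), sum(mol == "atorvastatin"), TRUE)
  dose[mol == "rosuvastatin"] <- sample(c(10, 20), sum(mol == "rosuvastatin"), TRUE)
  dose[mol == "pravastatin"] <- 40
  dose[mol == "fluvastatin"] <- 80
  list(molecule = mol, dose = dose)
}

# Down-titration (from, to) pairs; same-molecule pairs drop dose, cross-
# molecule pairs drop intensity class (atorvastatin 40 is the archetype).
dt_same_pairs <- tibble::tribble(
  ~molecule, ~dose_hi, ~dose_lo,
  "atorvastatin", 40, 20,
  "atorvastatin", 80, 40,
  "simvastatin",  40, 20,
  "rosuvastatin", 20, 10
)
dt_diff_pairs <- tibble::tribble(
  ~mol_hi, ~dose_hi, ~mol_lo, ~dose_lo,
  "atorvastatin", 40, "simvastatin", 20,   # high -> moderate
  "rosuvastatin", 20, "atorvastatin", 20,  # high -> moderate
  "atorvastatin", 20, "pravastatin", 20    # moderate -> low
)
switch_pairs <- tibble::tribble(
  ~mol_a, ~dose_a, ~mol_b, ~dose_b,
  "simvastatin", 20, "atorvastatin", 20,   # moderate -> moderate
  "simvastatin", 40, "atorvastatin", 20
)

sign_options <- c("dt_same", "dt_diff", "multi", "intermittent",
                  "prior_disc", "sams", "documented")
sign_weights <- c(0.35, 0.15, 0.10, 0.10, 0.10, 0.15, 0.05)

sample_sams_code <- function(n) {
  sample(c("M79.1", "R25.2", "M60.9", "G72.0"), n, replace = TRUE,
         prob = c(0.45, 0.40, 0.05, 0.10))
}

# Build the class-defining statin/non-statin trajectory for a block of
# patients sharing one planted class. Returns prescriptions, sign diagnoses
# and per-patient flags (documented_si plant, forced subgroup).
plant_class_block <- function(class, ids, study) {
  n <- length(ids)
  end <- study$study_end
  rx <- list(); dg <- list()
  documented <- rep(FALSE, n)
  force_cv <- rep(FALSE, n)   # force an ASCVD / high-CV-risk qualifying code

  active_target <- function(m) rand_dates(m, as.Date("2020-01-15"), as.Date("2020-03-15"))

  if (class == "tolerant") {
    st <- sample_maintenance_statin(n)
    start <- rand_dates(n, as.Date("2018-03-01"), as.Date("2019-03-01"))
    tgt <- active_target(n)
    rx[[1]] <- segments_to_scripts(tibble::tibble(
      patient_id = ids, molecule = st$molecule, dose_mg = st$dose,
      n = n_refills(start, tgt, 30L), start = start, interval = 30L))
  } else if (class == "absolute_high") {
    variant <- sample(c("nonstatin", "discontinued"), n, TRUE, prob = c(0.25, 0.75))
    # AH1: ASCVD / high-CV-risk patients only on non-statin LLTs
    i1 <- which(variant == "nonstatin")
    if (length(i1)) {
      force_cv[i1] <- TRUE
      mol <- sample(names(nonstatin_atc_codes), length(i1), TRUE,
                    prob = c(0.55, 0.25, 0.20))
      start <- rand_dates(length(i1), as.Date("2018-03-01"), as.Date("2019-06-01"))
      tgt <- active_target(length(i1))
      rx[[length(rx) + 1L]] <- segments_to_scripts(tibble::tibble(
        patient_id = ids[i1], molecule = mol, dose_mg = NA_real_,
        n = n_refills(start, tgt, 30L), start = start, interval = 30L))
    }
    # AH2: statin history ending >gap before study end, plus one sign event
    i2 <- which(variant == "discontinued")
    if (length(i2)) {
      parts <- plant_discontinued_with_sign(ids[i2], study)
      rx[[length(rx) + 1L]] <- parts$rx
      dg[[length(dg) + 1L]] <- parts$dg
      documented[i2] <- parts$documented
    }
  } else if (class == "absolute_low") {
    # regular refills at a constant moderate dose, stopping early, no signs
    st <- sample_maintenance_statin(n)
    start <- rand_dates(n, as.Date("2017-03-01"), as.Date("2017-10-01"))
    rx[[1]] <- segments_to_scripts(tibble::tibble(
      patient_id = ids, molecule = st$molecule, dose_mg = st$dose,
      n = sample(8:16, n, TRUE), start = start, interval = 30L))
  } else if (class == "partial_high") {
    parts <- plant_active_with_sign(ids, study)
    rx[[1]] <- parts$rx
    dg[[1]] <- parts$dg
    documented <- parts$documented
  } else if (class == "partial_low") {
    variant <- sample(c("low_intensity", "switch"), n, TRUE, prob = c(0.6, 0.4))
    i1 <- which(variant == "low_intensity")
    if (length(i1)) {
      # PL1: low-intensity (but not lowest-dose) statin, active, no signs
      force_cv[i1] <- TRUE
      pick <- sample(1:2, length(i1), TRUE)
      mol <- c("pravastatin", "fluvastatin")[pick]
      dose <- c(20, 40)[pick]
      start <- rand_dates(length(i1), as.Date("2018-03-01"), as.Date("2019-03-01"))
      tgt <- active_target(length(i1))
      rx[[length(rx) + 1L]] <- segments_to_scripts(tibble::tibble(
        patient_id = ids[i1], molecule = mol, dose_mg = dose,
        n = n_refills(start, tgt, 30L), start = start, interval = 30L))
    }
    i2 <- which(variant == "switch")
    if (length(i2)) {
      # PL2: one clean intensity-preserving molecule switch, active
      pr <- switch_pairs[sample(nrow(switch_pairs), length(i2), TRUE), ]
      start <- rand_dates(length(i2), as.Date("2018-03-01"), as.Date("2018-10-01"))
      n1 <- sample(5:9, length(i2), TRUE)
      s2 <- start + n1 * 30L
      tgt <- active_target(length(i2))
      rx[[length(rx) + 1L]] <- segments_to_scripts(dplyr::bind_rows(
        tibble::tibble(patient_id = ids[i2], molecule = pr$mol_a, dose_mg = pr$dose_a,
                       n = n1, start = start, interval = 30L),
        tibble::tibble(patient_id = ids[i2], molecule = pr$mol_b, dose_mg = pr$dose_b,
                       n = n_refills(s2, tgt, 30L), start = s2, interval = 30L)))
    }
  }
  list(rx = dplyr::bind_rows(rx),
       dg = if (length(dg)) dplyr::bind_rows(dg) else NULL,
       documented = documented, force_cv = force_cv)
}

# Statin history that ends long before study end (permanent discontinuation)
# carrying exactly one high-confidence sign event. Intermittent dosing is not
# plantable here: the adherence-ratio detector only applies to histories that
# are not permanently discontinued.
plant_discontinued_with_sign <- function(ids, study) {
  n <- length(ids)
  opts <- setdiff(sign_options, "intermittent")
  w <- sign_weights[match(opts, sign_options)]
  sign <- sample(opts, n, TRUE, prob = w / sum(w))
  start <- rand_dates(n, as.Date("2017-03-01"), as.Date("2017-10-01"))
  seg <- list(); dg <- NULL
  add <- function(x) seg[[length(seg) + 1L]] <<- x

  i <- which(sign %in% c("sams", "documented"))
  if (length(i)) {
    st <- sample_maintenance_statin(length(i))
    nn <- sample(8:14, length(i), TRUE)
    add(tibble::tibble(patient_id = ids[i], molecule = st$molecule,
                       dose_mg = st$dose, n = nn, start = start[i], interval = 30L))
    is_sams <- sign[i] == "sams"
    if (any(is_sams)) {
      j <- i[is_sams]
      span <- (nn[is_sams] - 1L) * 30L
      dg <- tibble::tibble(patient_id = ids[j],
                           date = start[j] + floor(runif(length(j)) * pmax(span, 1)),
                           icd10 = sample_sams_code(length(j)))
    }
  }
  i <- which(sign == "dt_same")
  if (length(i)) {
    pr <- dt_same_pairs[sample(nrow(dt_same_pairs), length(i), TRUE), ]
    n1 <- sample(5:9, length(i), TRUE)
    add(tibble::tibble(patient_id = ids[i], molecule = pr$molecule,
                       dose_mg = pr$dose_hi, n = n1, start = start[i], interval = 30L))
    add(tibble::tibble(patient_id = ids[i], molecule = pr$molecule,
                       dose_mg = pr$dose_lo, n = sample(2:4, length(i), TRUE),
                       start = start[i] + n1 * 30L, interval = 30L))
  }
  i <- which(sign == "dt_diff")
  if (length(i)) {
    pr <- dt_diff_pairs[sample(nrow(dt_diff_pairs), length(i), TRUE), ]
    n1 <- sample(5:9, length(i), TRUE)
    add(tibble::tibble(patient_id = ids[i], molecule = pr$mol_hi,
                       dose_mg = pr$dose_hi, n = n1, start = start[i], interval = 30L))
    add(tibble::tibble(patient_id = ids[i], molecule = pr$mol_lo,
                       dose_mg = pr$dose_lo, n = sample(2:4, length(i), TRUE),
                       start = start[i] + n1 * 30L, interval = 30L))
  }
  i <- which(sign == "multi")
  if (length(i)) {
    # alternation simva -> atorva -> simva at preserved (moderate) intensity
    add(tibble::tibble(patient_id = ids[i], molecule = "simvastatin", dose_mg = 20,
                       n = 3L, start = start[i], interval = 30L))
    add(tibble::tibble(patient_id = ids[i], molecule = "atorvastatin", dose_mg = 10,
                       n = 3L, start = start[i] + 90L, interval = 30L))
    add(tibble::tibble(patient_id = ids[i], molecule = "simvastatin", dose_mg = 20,
                       n = 3L, start = start[i] + 180L, interval = 30L))
  }
  i <- which(sign == "prior_disc")
  if (length(i)) {
    st <- sample_maintenance_statin(length(i))
    extra <- sample(211:280, length(i), TRUE)
    add(tibble::tibble(patient_id = ids[i], molecule = st$molecule,
                       dose_mg = st$dose, n = 4L, start = start[i], interval = 30L))
    add(tibble::tibble(patient_id = ids[i], molecule = st$molecule,
                       dose_mg = st$dose, n = 4L,
                       start = start[i] + 120L + extra, interval = 30L))
  }
  list(rx = segments_to_scripts(dplyr::bind_rows(seg)), dg = dg,
       documented = sign == "documented")
}

# Active statin history (no terminal gap) carrying one sign event.
plant_active_with_sign <- function(ids, study) {
  n <- length(ids)
  sign <- sample(sign_options, n, TRUE, prob = sign_weights)
  sign[sign == "dt_diff"] <- "dt_same"   # keep one dt flavour dominant here
  start <- rand_dates(n, as.Date("2018-03-01"), as.Date("2018-09-01"))
  tgt <- rand_dates(n, as.Date("2020-02-01"), as.Date("2020-03-15"))
  seg <- list(); dg <- NULL
  add <- function(x) seg[[length(seg) + 1L]] <<- x

  i <- which(sign %in% c("sams", "documented"))
  if (length(i)) {
    st <- sample_maintenance_statin(length(i))
    add(tibble::tibble(patient_id = ids[i], molecule = st$molecule, dose_mg = st$dose,
                       n = n_refills(start[i], tgt[i], 30L), start = start[i],
                       interval = 30L))
    is_sams <- sign[i] == "sams"
    if (any(is_sams)) {
      j <- i[is_sams]
      dg <- tibble::tibble(patient_id = ids[j],
                           date = rand_dates(length(j), as.Date("2018-10-01"),
                                             as.Date("2020-03-01")),
                           icd10 = sample_sams_code(length(j)))
    }
  }
  i <- which(sign == "dt_same")
  if (length(i)) {
    pr <- dt_same_pairs[sample(nrow(dt_same_pairs), length(i), TRUE), ]
    n1 <- sample(6:10, length(i), TRUE)
    s2 <- start[i] + n1 * 30L
    add(tibble::tibble(patient_id = ids[i], molecule = pr$molecule,
                       dose_mg = pr$dose_hi, n = n1, start = start[i], interval = 30L))
    add(tibble::tibble(patient_id = ids[i], molecule = pr$molecule,
                       dose_mg = pr$dose_lo, n = n_refills(s2, tgt[i], 30L),
                       start = s2, interval = 30L))
  }
  i <- which(sign == "multi")
  if (length(i)) {
    s2 <- start[i] + 120L
    s3 <- start[i] + 240L
    add(tibble::tibble(patient_id = ids[i], molecule = "simvastatin", dose_mg = 20,
                       n = 4L, start = start[i], interval = 30L))
    add(tibble::tibble(patient_id = ids[i], molecule = "atorvastatin", dose_mg = 10,
                       n = 4L, start = s2, interval = 30L))
    add(tibble::tibble(patient_id = ids[i], molecule = "simvastatin", dose_mg = 20,
                       n = n_refills(s3, tgt[i], 30L), start = s3, interval = 30L))
  }
  i <- which(sign == "intermittent")
  if (length(i)) {
    iv <- sample(90:110, length(i), TRUE)
    add(tibble::tibble(patient_id = ids[i],
                       molecule = sample_maintenance_statin(length(i))$molecule,
                       dose_mg = 20, n = n_refills(start[i], tgt[i], iv),
                       start = start[i], interval = iv))
  }
  i <- which(sign == "prior_disc")
  if (length(i)) {
    st <- sample_maintenance_statin(length(i))
    n1 <- sample(3:5, length(i), TRUE)
    s2 <- start[i] + n1 * 30L + sample(211:260, length(i), TRUE)
    add(tibble::tibble(patient_id = ids[i], molecule = st$molecule, dose_mg = st$dose,
                       n = n1, start = start[i], interval = 30L))
    add(tibble::tibble(patient_id = ids[i], molecule = st$molecule, dose_mg = st$dose,
                       n = n_refills(s2, tgt[i], 30L), start = s2, interval = 30L))
  }
  list(rx = segments_to_scripts(dplyr::bind_rows(seg)), dg = dg,
       documented = sign == "documented")
}

#' Plant the class-defining trajectory for a single patient
#'
#' Exposes the generator's trajectory templates one patient at a time: given a
#' planted phenotype label, returns the prescriptions and sign-event diagnoses
#' that make the rule engine map the patient back to that label (given a
#' qualifying diagnosis and eligibility events, which [generate_cohort()]
#' adds).
#'
#' @param planted_class One of `tolerant`, `absolute_high`, `absolute_low`,
#'   `partial_high`, `partial_low`.
#' @param study A [study_config()].
#' @param patient_id Identifier for the generated rows.
#' @return List with `prescriptions`, `diagnoses`, `documented_si`
#'   (logical), `force_cv` (logical: the patient requires an ASCVD or
#'   high-CV-risk qualifying code).
#' @export
plant_trajectory <- function(planted_class, study = study_config(),
                             patient_id = "P1") {
  assert_that(planted_class %in% si_labels(),
              paste0("unknown class: ", planted_class))
  parts <- plant_class_block(planted_class, patient_id, study)
  dg <- parts$dg %||% tibble::tibble(patient_id = character(),
                                     date = as.Date(character()),
                                     icd10 = character())
  list(prescriptions = parts$rx, diagnoses = dg,
       documented_si = parts$documented, force_cv = parts$force_cv)
}

qualifying_code_pool <- list(
  ascvd = c("I25.1", "I20.0", "I63.9", "I70.2"),
  high_cv_risk = c("E11.9", "E10.9"),
  hypercholesterolemia = c("E78.0", "E78.2")
)

stochastic_event_codes <- c(myalgia = "M79.1", cramps = "R25.2",
                            myositis = "M60.9", myopathy = "G72.0",
                            vitamin_d = "E55.9", hypothyroidism = "E03.9",
                            obesity = "E66.0", ckd = "N18.3")
stochastic_event_rx <- c(fibrate_use = "fenofibrate", ezetimibe_use = "ezetimibe")
visit_code_pool <- c("I10", "J06.9", "M54.5", "K21.0", "H52.4")

#' Generate a synthetic EMR cohort with planted ground truth
#'
#' Simulates eligible outpatients: everyone is an adult with a qualifying
#' diagnosis, a consultation in the selection window and lipid-lowering
#' therapy in the study period. Each patient carries the trajectory of their
#' planted phenotype; truly intolerant patients additionally draw the signal
#' features (muscle-symptom codes, fibrate/ezetimibe use, visit volume) at
#' `signal_effects`-scaled rates. All randomness flows from `scenario$seed`;
#' identical seeds give identical cohorts.
#'
#' @param scenario A [scenario_config()].
#' @param study A [study_config()].
#' @return List with `cohort` (an [emr_cohort()]) and `ground_truth` (tibble
#'   `patient_id`, `planted_class`, `latent_intolerant`).
#' @export
generate_cohort <- function(scenario, study = study_config()) {
  assert_that(inherits(scenario, "scenario_config"),
              "scenario must be a scenario_config")
  set.seed(scenario$seed, kind = "Mersenne-Twister")
  n <- scenario$n_patients
  ids <- sprintf("P%06d", seq_len(n))
  classes <- sample(si_labels(), n, TRUE, prob = scenario$class_mix)

  latent <- classes %in% c("absolute_high", "partial_high") |
    (classes %in% c("absolute_low", "partial_low") &
       runif(n) < scenario$latent_si_given_low_conf)

  rx <- list(); dg <- list()
  documented <- rep(FALSE, n); force_cv <- rep(FALSE, n)
  for (cl in si_labels()) {
    idx <- which(classes == cl)
    if (!length(idx)) next
    parts <- plant_class_block(cl, ids[idx], study)
    rx[[cl]] <- parts$rx
    if (!is.null(parts$dg)) dg[[cl]] <- parts$dg
    documented[idx] <- parts$documented
    force_cv[idx] <- parts$force_cv
  }

  # qualifying diagnosis inside the selection window: guarantees both the
  # consultation criterion and a non-empty subgroup
  sub_pick <- sample(names(qualifying_code_pool), n, TRUE, prob = c(0.56, 0.21, 0.23))
  sub_pick[force_cv] <- sample(c("ascvd", "high_cv_risk"), sum(force_cv), TRUE,
                               prob = c(0.75, 0.25))
  qcode <- vapply(qualifying_code_pool[sub_pick],
                  function(p) p[sample.int(length(p), 1L)], character(1))
  dg$qualifying <- tibble::tibble(
    patient_id = ids,
    date = rand_dates(n, study$selection_start, study$selection_end),
    icd10 = qcode)

  # stochastic signal / comorbidity events, elevated for latent intolerance
  br <- scenario$baseline_rates
  se <- scenario$signal_effects
  event_window <- c(as.Date("2018-07-01"), as.Date("2020-03-01"))
  for (ev in setdiff(names(br), c("visit_count", "documented_si"))) {
    rr <- if (ev %in% names(se)) se[[ev]] else 1
    p <- pmin(br[[ev]] * ifelse(latent, rr, 1), 0.95)
    hit <- which(runif(n) < p)
    if (!length(hit)) next
    if (ev %in% names(stochastic_event_codes)) {
      reps <- sample(1:2, length(hit), TRUE)
      r <- rep(hit, reps)
      dg[[ev]] <- tibble::tibble(
        patient_id = ids[r],
        date = rand_dates(length(r), event_window[1], event_window[2]),
        icd10 = stochastic_event_codes[[ev]])
    } else if (ev %in% names(stochastic_event_rx)) {
      mol <- stochastic_event_rx[[ev]]
      reps <- sample(2:6, length(hit), TRUE)
      r <- rep(hit, reps)
      rx[[ev]] <- tibble::tibble(
        patient_id = ids[r],
        date = rand_dates(length(r), event_window[1], event_window[2]),
        atc = nonstatin_atc_codes[[mol]], molecule = mol,
        dose_mg = NA_real_, days_supplied = NA_integer_)
    }
  }
  if (br[["documented_si"]] > 0) {
    documented <- documented | (runif(n) < br[["documented_si"]])
  }

  # visit volume: extra benign consultation diagnoses
  if (br[["visit_count"]] > 0) {
    lam <- br[["visit_count"]] * ifelse(latent, se[["visit_count"]], 1)
    nv <- rpois(n, lam)
    r <- rep(seq_len(n), nv)
    if (length(r)) {
      dg$visits <- tibble::tibble(
        patient_id = ids[r],
        date = rand_dates(length(r), event_window[1], event_window[2]),
        icd10 = sample(visit_code_pool, length(r), TRUE))
    }
  }

  # pure-noise diagnosis codes, independent of phenotype
  if (scenario$n_noise_features > 0) {
    noise_codes <- sprintf("Z%02d", 10 + seq_len(scenario$n_noise_features))
    hits <- which(matrix(runif(n * length(noise_codes)), n) < scenario$noise_feature_rate,
                  arr.ind = TRUE)
    if (nrow(hits)) {
      dg$noise <- tibble::tibble(
        patient_id = ids[hits[, 1]],
        date = rand_dates(nrow(hits), event_window[1], event_window[2]),
        icd10 = noise_codes[hits[, 2]])
    }
  }

  age <- pmin(pmax(round(rnorm(n, 72, 12)), 25), 98)
  patients <- tibble::tibble(
    patient_id = ids,
    birth_year = 2019L - as.integer(age),
    gender = sample(c("female", "male", "unspecified"), n, TRUE,
                    prob = c(0.442, 0.556, 0.002)),
    documented_si_note = documented)

  cohort <- emr_cohort(patients, dplyr::bind_rows(dg), dplyr::bind_rows(rx))
  ground_truth <- tibble::tibble(patient_id = ids, planted_class = classes,
                                 latent_intolerant = latent)
  list(cohort = cohort, ground_truth = ground_truth)
}

#' Simulate a cohort and write it to disk
#'
#' Runs [generate_cohort()] and writes the three EMR tables plus
#' `ground_truth.csv` to `dir`.
#'
#' @inheritParams generate_cohort
#' @param dir Output directory.
#' @return Invisibly, the ground-truth tibble.
#' @export
simulate_emr <- function(scenario, dir, study = study_config()) {
  out <- generate_cohort(scenario, study)
  write_emr(out$cohort, dir)
  readr::write_csv(out$ground_truth, file.path(dir, "ground_truth.csv"),
                   progress = FALSE)
  invisible(out$ground_truth)
}
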