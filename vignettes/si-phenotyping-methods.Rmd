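---
title: "Statin-intolerance phenotyping and prevalence calibration: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Statin-intolerance phenotyping and prevalence calibration: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The estimation problem

Statin intolerance (SI) — most often statin-associated muscle symptoms (SAMS)
— is rarely coded explicitly in outpatient electronic medical records. Its
prevalence must therefore be inferred from *treatment behaviour*: dose
reductions, molecule changes, sparse refills, and treatment abandonment in
patients who still carry an indication for lipid-lowering therapy. `sipheno`
implements a two-stage estimator over longitudinal EMR extracts:

1. a **deterministic rule engine** maps each patient's statin event profile to
   one of five labels — `tolerant`, absolute or partial intolerance, each at
   high or low confidence;
2. a **supervised calibration step** treats the high-confidence patients as
   reference positives, trains high-confidence-versus-tolerant classifiers,
   and uses them to decide which *low-confidence* patients are truly
   intolerant, updating the prevalence estimate while conserving totals.

Absolute intolerance means the patient cannot take statins at all (no active
statin therapy); partial intolerance means statins continue at a reduced or
irregular exposure.

## Study design conventions

All date intervals are half-open `[start, end)` and dates are ISO-8601. The
default `study_config()` uses a March 2017 – March 2020 study period, a
March 2019 – March 2020 selection window (every cohort member needs one
consultation there), a 730-day lookback from the index date (never before the
study start), a 180-day discontinuation gap, a default 30-day script supply,
and a 0.5 medication-possession-ratio (MPR) cutoff. Eligibility is applied in
a fixed, counted order: adult at index → consultation in the selection window
→ lipid-lowering prescription in the study period → qualifying diagnosis
(ASCVD, high cardiovascular risk, or hypercholesterolemia) at any time before
the selection window closes. The index date is the latest statin script in the
study period, falling back to the latest non-statin lipid-lowering script.

## Event detectors

All detectors operate on the patient's statin exposure inside
`[lookback_start, study_end)`:

* **Down-titration**, same molecule: consecutive scripts with a strictly lower
  dose. Different molecule: consecutive scripts with a strictly lower
  *intensity class* (see below). Same-day script pairs are concurrent
  prescribing, never transitions.
* **Switch**: a molecule change at unchanged intensity — deliberately distinct
  from down-titration.
* **Multi-statin use**: molecule plurality beyond one clean switch — three or
  more distinct molecules, a return to a previously used molecule, or two
  molecules prescribed on the same day. A single `A → B` switch is *not*
  multi-statin use; `A → B → A` is. This operationalisation keeps the switch
  and multi-statin signals disjoint for simple treatment paths.
* **Discontinuation**: script coverage ends at `date + days_supplied`.
  *Permanent* iff the gap from the last coverage end to the study end strictly
  exceeds 180 days; *prior* iff any internal gap does. An exact 180-day gap is
  therefore not a discontinuation.
* **Intermittent dosing**: an MPR — total days supplied over the covered span
  — strictly below 0.5, for histories with at least three scripts that are
  *not* permanently discontinued. A consequence of the not-discontinued
  precondition is that intermittent dosing can never be the distinguishing
  sign of a permanently discontinued patient; the synthetic generator
  respects this and only plants intermittent trajectories for patients who
  remain on therapy.
* **Low-dose use**: every script at or below the molecule's lowest marketed
  dose. This is *not* the same as low intensity: pravastatin 20 mg is
  low-intensity but above its lowest marketed dose.
* **SAMS**: any muscle-symptom diagnosis (myalgia, myositis, myopathy,
  cramps/spasms code sets) in the lookback window.
* **Documented intolerance**: a structured flag standing in for free-text
  intolerance/allergy notes.

Statin intensity uses a conventional low/moderate/high banding per molecule
and dose; doses outside every band take the nearest band, ties resolving to
the lower class.

## The rule table

Clauses are evaluated in fixed order; the first match wins. The AH2/PH sign
set is {down-titration (either kind), low-dose use, multi-statin use, SAMS,
intermittent dosing, documented intolerance, prior discontinuation} — a bare
switch is deliberately *not* a high-confidence sign and contributes only
through PL2.

| order | rule | label | condition |
|---|---|---|---|
| 1 | AH1 | absolute, high | ASCVD/high-CV-risk, no statin history (non-statin lipid-lowering therapy only) |
| 2 | AH2 | absolute, high | permanent discontinuation + at least one sign |
| 3 | PH  | partial, high  | active statin use + at least one sign |
| 4 | AL  | absolute, low  | permanent discontinuation, no sign (exclusions include switch) |
| 5 | PL1 | partial, low   | ASCVD/high-CV-risk, exclusively low-intensity statins, no sign |
| 6 | PL2 | partial, low   | no intermittent dosing, no permanent discontinuation, with a down-titration or switch |
| 7 | —   | tolerant       | everything else |

Patients with neither statin history nor an ASCVD/high-CV-risk tag cannot be
placed by the table; they fall through to `tolerant` and are flagged
`unclassifiable` for diagnostics.

## Supervised calibration

For each class $c \in \{\text{absolute}, \text{partial}\}$ the training set is
all high-confidence patients of $c$ (positives) against a seeded sample of up
to 50,000 rule-tolerant patients (negatives); low-confidence patients are
held out as the prediction target. Features are presence/count indicators per
3-character ICD-10 group and level-4 ATC class, demographics, and utilisation
counts, reduced by univariate mutual information (top-$k$, deterministic
tie-break by column order).

Mutual information $I(X;Y)$ is estimated in nats: features with at most 20
distinct values use the plug-in estimator on the joint contingency table;
continuous features use the mixed discrete–continuous k-nearest-neighbour
estimator
$$\hat I = \psi(N) + \psi(k) - \overline{\psi(n_{y_i})} - \overline{\psi(m_i)},$$
where $n_{y_i}$ is the size of point $i$'s class and $m_i$ counts points of
any class strictly inside the distance to $i$'s $k$-th within-class
neighbour. Estimates are clipped at zero; the 1-D implementation is
$O(n \log n)$.

Three model families — logistic regression, gradient-boosted trees, and the
DART boosting variant — are compared on identical stratified 4-fold splits;
the family with the highest mean F1 wins and is refit on the full set. The
decision threshold is tuned on the pooled out-of-fold scores to the
**precision-equals-recall point**: the candidate threshold (midpoints between
consecutive unique scores plus one candidate below and above) minimising
$|P - R|$, ties resolving to the lowest threshold, with $P = 1$ by convention
when nothing is predicted positive. At $P = R$ the false positives equal the
false negatives, so the *count* of predicted intolerant patients is an
unbiased plug-in for the count of true intolerant patients — precisely the
quantity prevalence estimation needs, which is why this operating point is
used rather than, say, maximum F1.

Low-confidence patients scoring at or above the threshold move into the
matching high-confidence cell. `update_prevalence` performs this move under
explicit conservation constraints: the total, the tolerant count and the
combined SI count are identical before and after. Attributions use exact
TreeSHAP values for tree families and permutation importance (ROC-AUC drop)
for the logistic family.

## Synthetic generator and its scope

`generate_cohort()` plants one of the five labels per patient (default mix
0.766/0.064/0.094/0.028/0.048) with a class-defining trajectory built from
the same event vocabulary the detectors read: maintenance refills for
tolerant patients, non-statin-only or discontinued-with-sign histories for
absolute high, early-stopping refills for absolute low, active-with-sign
histories for partial high, and low-intensity or clean-switch trajectories
for partial low. A latent intolerance flag — true for all high-confidence
patients and for a configurable fraction $\pi$ of low-confidence patients —
drives stochastic signal features (muscle-symptom codes, fibrate/ezetimibe
co-prescription, visit volume) at configurable rate ratios over tolerant
baselines, alongside pure-noise codes. All randomness flows from a single
seed; `noiseless_scenario()` switches every stochastic rate off, in which
case the rule engine recovers 100% of planted labels.

The generator emulates the *structure* of an outpatient claims-like extract,
not any real population: baseline rates and effect sizes are conventional
stand-ins, trajectories are cleaner than real prescribing, and coding
practice variation is not modelled. It exists to make every pipeline stage
testable with known ground truth, including end-to-end prevalence recovery:
on cohorts of 20,000 patients the post-calibration high-confidence share
tracks the identifiable target (rule-high share $+\ \pi \cdot$ rule-low
share) within a few percentage points.

## Worked example

```{r, eval = FALSE}
library(sipheno)

g <- generate_cohort(scenario_config(5000, seed = 1))
sel <- select_cohort(g$cohort)
profiles <- build_event_profiles(g$cohort, sel$entries)
cls <- classify_cohort(sel$entries, profiles)
cls$counts

fm <- build_features(g$cohort, sel$entries)
cal <- calibrate_si(fm, cls$classifications, seed = 1)
cal$prevalence
```

`run_pipeline()` wraps the same flow for an on-disk extract and writes the
attrition, classification, prevalence, characteristics and transition-matrix
reports plus a reproducibility manifest.

## Problem sizes and limitations

The test suite exercises cohorts up to 20,000 patients; profile construction
is vectorised and handles that size in a few seconds. Known limitations:
the rule engine sees only what is coded (silent intolerance in patients who
never return is invisible); calibration assumes low-confidence intolerant
patients resemble high-confidence ones in feature space; the
precision-equals-recall threshold targets aggregate counts, not individual
accuracy; and the default code sets, intensity bands and lowest marketed
doses are editable conventions, not clinical advice.
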