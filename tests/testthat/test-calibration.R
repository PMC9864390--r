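# A linearly separable two-class feature matrix with patient-id rownames.
sep_matrix <- function(n, seed = 1, shift = 4) {
  set.seed(seed)
  y <- rep(c(0L, 1L), n / 2)
  x <- cbind(signal = rnorm(n) + shift * y, other = rnorm(n))
  rownames(x) <- sprintf("S%04d", seq_len(n))
  list(x = x, y = y)
}

mk_classifications <- function(ids, labels) {
  tibble::tibble(patient_id = ids,
                 label = factor(labels, levels = c(
                   "tolerant", "absolute_high", "absolute_low",
                   "partial_high", "partial_low")))
}

test_that("metric primitives match hand-computed values and the pROC oracle", {
  f1 <- sipheno:::f1_score
  expect_equal(f1(c(1, 1, 0, 0), c(1, 0, 1, 0)), 0.5)  # tp=1 fp=1 fn=1
  expect_equal(f1(c(1, 1), c(1, 1)), 1)
  expect_equal(f1(c(0, 0), c(1, 1)), 0)

  set.seed(51)
  scores <- runif(300)
  truth <- rbinom(300, 1, 0.4)
  ours <- sipheno:::roc_auc(scores, truth)
  oracle <- as.numeric(pROC::roc(truth, scores, direction = "<",
                                 quiet = TRUE)$auc)
  expect_equal(ours, oracle, tolerance = 1e-12)
  # perfect and random separation
  expect_equal(sipheno:::roc_auc(c(0.1, 0.9), c(0, 1)), 1)
  expect_equal(sipheno:::pr_auc(c(0.9, 0.8, 0.1), c(1, 1, 0)), 1)
  # average precision, hand-traced: positives at ranks 1 and 3
  expect_equal(sipheno:::pr_auc(c(0.9, 0.8, 0.7), c(1, 0, 1)),
               (1 + 2 / 3) / 2)
})

test_that("make_training_set samples negatives reproducibly and caps at availability", {
  n <- 200
  ids <- sprintf("S%04d", seq_len(n))
  x <- matrix(rnorm(n * 2), n, dimnames = list(ids, c("a", "b")))
  labels <- rep("tolerant", n)
  labels[1:30] <- "absolute_high"
  labels[31:40] <- "absolute_low"
  cls <- mk_classifications(ids, labels)
  ts <- make_training_set(x, cls, "absolute", n_tolerant = 50, seed = 7)
  expect_equal(sum(ts$y == 1), 30)
  expect_equal(sum(ts$y == 0), 50)
  # low-confidence patients never enter the training set
  expect_false(any(ids[31:40] %in% ts$patient_id))
  ts2 <- make_training_set(x, cls, "absolute", n_tolerant = 50, seed = 7)
  expect_identical(ts$patient_id, ts2$patient_id)
  # cap: asking for more tolerant than available returns them all
  ts3 <- make_training_set(x, cls, "absolute", n_tolerant = 10000, seed = 7)
  expect_equal(sum(ts3$y == 0), 160)
  expect_error(make_training_set(x, cls, "partial"),
               "no high-confidence partial")
})

test_that("cross-validation separates a separable problem and selects a family", {
  d <- sep_matrix(400, seed = 52)
  m <- crossval_train(d, seed = 1, families = c("logistic", "xgb_tree"),
                      nfolds = 4, nrounds = 20)
  means <- m$reports[is.na(m$reports$fold), ]
  expect_equal(nrow(means), 2)
  expect_equal(sum(means$selected), 1)
  expect_gt(means$f1[means$selected], 0.95)
  expect_gt(means$roc_auc[means$selected], 0.99)
  expect_equal(m$family, means$family[means$selected])
  expect_equal(nrow(m$oof), 400)
  # per-fold rows exist for every family/fold pair
  expect_equal(sum(!is.na(m$reports$fold)), 8)
})

test_that("shuffled labels give chance-level out-of-fold AUC", {
  set.seed(53)
  d <- sep_matrix(600, seed = 53)
  y_shuffled <- sample(d$y)
  m <- crossval_train(list(x = d$x, y = y_shuffled), seed = 2,
                      families = "xgb_tree", nrounds = 10)
  auc <- sipheno:::roc_auc(m$oof$score, m$oof$label)
  expect_gt(auc, 0.4)
  expect_lt(auc, 0.6)
})

test_that("predict_si guards the feature-name contract", {
  d <- sep_matrix(200, seed = 54)
  m <- crossval_train(d, seed = 1, families = "logistic")
  bad <- d$x[, c("other", "signal")]
  expect_error(predict_si(m, bad), "feature names")
  p <- predict_si(m, d$x)
  expect_true(all(p >= 0 & p <= 1))
})

test_that("find_threshold matches a hand-traced case exactly", {
  res <- find_threshold(c(0.9, 0.8, 0.4, 0.3), c(1, 1, 1, 0))
  # at 0.35 the three positives are predicted and the negative is not
  expect_equal(res$threshold, 0.35)
  expect_equal(res$precision, 1)
  expect_equal(res$recall, 1)
  expect_equal(res$gap, 0)
})

test_that("a no-positive-prediction threshold has precision 1 by convention", {
  res <- find_threshold(c(0.2, 0.1), c(0, 1))
  # the score order is inverted, so the best achievable gap favours
  # predicting only the top score: P = 0, R = 0 at t = 0.15 gives gap 0
  expect_equal(res$gap, 0)
  expect_equal(res$threshold, 0.15)
})

test_that("find_threshold matches the exhaustive oracle on random inputs", {
  set.seed(55)
  for (i in 1:20) {
    scores <- round(runif(100), 2)
    labels <- rbinom(100, 1, runif(1, 0.2, 0.8))
    if (length(unique(labels)) < 2) next
    res <- find_threshold(scores, labels)
    oracle <- threshold_oracle(scores, labels)
    expect_equal(res$gap, oracle$gap, tolerance = 1e-12)
    expect_equal(res$threshold, oracle$threshold)
  }
})

test_that("at a zero-gap threshold false positives equal false negatives", {
  set.seed(56)
  scores <- runif(500)
  labels <- as.integer(runif(500) < scores)   # calibrated scores
  res <- find_threshold(scores, labels)
  pred <- scores >= res$threshold
  fp <- sum(pred & labels == 0)
  fn <- sum(!pred & labels == 1)
  if (res$gap == 0) expect_equal(fp, fn)
  # and generally the predicted-positive count is close to the positive count
  expect_lt(abs(sum(pred) - sum(labels)), 0.1 * sum(labels))
})

test_that("reclassification recovers the planted intolerance fraction at the extremes", {
  d <- sep_matrix(800, seed = 57)
  m <- crossval_train(d, seed = 3, families = "xgb_tree", nrounds = 20)
  thr <- find_threshold(m$oof$score, m$oof$label)
  draw <- function(n, from_positive, seed) {
    set.seed(seed)
    x <- cbind(signal = rnorm(n) + 4 * from_positive, other = rnorm(n))
    rownames(x) <- sprintf("L%04d", seq_len(n))
    x
  }
  all_pos <- reclassify_low_confidence(m, thr$threshold, draw(200, 1, 58))
  expect_gt(mean(all_pos$predicted == "intolerant"), 0.95)
  all_neg <- reclassify_low_confidence(m, thr$threshold, draw(200, 0, 59))
  expect_lt(mean(all_neg$predicted == "intolerant"), 0.05)
  empty <- reclassify_low_confidence(m, thr$threshold, d$x[0, , drop = FALSE])
  expect_equal(nrow(empty), 0)
})

test_that("update_prevalence moves counts between cells and validates inputs", {
  rc <- c(tolerant = 700, absolute_high = 100, absolute_low = 80,
          partial_high = 70, partial_low = 50)
  out <- update_prevalence(rc, 30, 20)
  after <- out[out$stage == "rules_plus_ml", ]
  expect_equal(after$count[after$label == "absolute_high"], 130)
  expect_equal(after$count[after$label == "absolute_low"], 50)
  expect_equal(after$count[after$label == "partial_high"], 90)
  expect_equal(after$count[after$label == "partial_low"], 30)
  expect_equal(after$count[after$label == "tolerant"], 700)
  expect_equal(unique(out$count[out$label == "total"]), 1000)
  expect_equal(after$pct[after$label == "absolute_high"], 13)
  expect_error(update_prevalence(rc, 81, 0), "more absolute")
  expect_error(update_prevalence(rc, -1, 0), "non-negative")
  expect_error(update_prevalence(c(tolerant = 10), 0, 0), "all five labels")
})

test_that("prevalence_increase derives from the printed one-decimal percentages", {
  rc <- c(tolerant = 800, absolute_high = 64, absolute_low = 60,
          partial_high = 40, partial_low = 36)
  out <- update_prevalence(rc, 17, 0)
  # 6.4% -> 8.1%: 100 * 1.7 / 6.4
  expect_equal(prevalence_increase(out, "absolute"), 100 * 1.7 / 6.4,
               tolerance = 1e-9)
})

test_that("feature importance puts the signal feature first for both family kinds", {
  d <- sep_matrix(400, seed = 60)
  tree <- crossval_train(d, seed = 4, families = "xgb_tree", nrounds = 20)
  imp_tree <- feature_importance(tree, d$x)
  expect_equal(imp_tree$feature[1], "signal")
  logit <- crossval_train(d, seed = 4, families = "logistic")
  imp_log <- feature_importance(logit, d$x, d$y, seed = 5)
  expect_equal(imp_log$feature[1], "signal")
  expect_error(feature_importance(logit, d$x), "needs labels")
})

test_that("calibrate_si reclassifies only low-confidence patients and conserves totals", {
  g <- generate_cohort(scenario_config(3000, seed = 61))
  sel <- select_cohort(g$cohort)
  cls <- classify_cohort(sel$entries, build_event_profiles(g$cohort, sel$entries))
  fm <- build_features(g$cohort, sel$entries)
  cal <- calibrate_si(fm, cls$classifications, k_features = 25, seed = 61,
                      families = "xgb_tree", nrounds = 10)
  low_ids <- cls$classifications$patient_id[
    cls$classifications$label %in% c("absolute_low", "partial_low")]
  expect_true(all(cal$reclassified$patient_id %in% low_ids))
  prev <- cal$prevalence
  for (lab in c("total", "tolerant")) {
    expect_equal(prev$count[prev$stage == "rules_only" & prev$label == lab],
                 prev$count[prev$stage == "rules_plus_ml" & prev$label == lab])
  }
  si_sum <- function(stage) sum(prev$count[prev$stage == stage &
    prev$label %in% c("absolute_high", "absolute_low",
                      "partial_high", "partial_low")])
  expect_equal(si_sum("rules_only"), si_sum("rules_plus_ml"))
  expect_named(cal$models, c("absolute", "partial"))
  expect_true(all(vapply(cal$thresholds, function(t)
    t$threshold > 0 && t$threshold < 1, logical(1))))
})
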