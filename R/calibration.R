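#' Assemble a training set for one calibration task
#'
#' Positives are all high-confidence patients of the task's class (absolute or
#' partial); negatives are a seeded uniform random sample of rule-tolerant
#' patients (without replacement, capped at the number available).
#' Low-confidence patients are excluded — they are the prediction target.
#'
#' @param fm A `feature_matrix` from [build_features()].
#' @param classifications Classification tibble from [classify_cohort()].
#' @param class `"absolute"` or `"partial"`.
#' @param n_tolerant Size of the tolerant sample (default 50000).
#' @param seed Integer seed for the sample.
#' @return An `si_training_set`: list `x` (matrix), `y` (0/1 integer),
#'   `patient_id`.
#' @export
make_training_set <- function(fm, classifications, class = c("absolute", "partial"),
                              n_tolerant = 50000L, seed = 1L) {
  class <- match.arg(class)
  x <- if (inherits(fm, "feature_matrix")) fm$x else fm
  cls <- classifications
  pos_ids <- cls$patient_id[cls$label == paste0(class, "_high")]
  assert_that(length(pos_ids) > 0,
              paste0("no high-confidence ", class, " patients to train on"))
  tol_ids <- cls$patient_id[cls$label == "tolerant"]
  assert_that(length(tol_ids) > 0, "no tolerant patients to sample negatives from")
  set.seed(seed)
  if (n_tolerant < length(tol_ids)) {
    neg_ids <- sample(tol_ids, n_tolerant)
  } else {
    neg_ids <- tol_ids
  }
  ids <- c(pos_ids, neg_ids)
  assert_that(all(ids %in% rownames(x)),
              "classification ids missing from the feature matrix")
  structure(list(x = x[ids, , drop = FALSE],
                 y = c(rep(1L, length(pos_ids)), rep(0L, length(neg_ids))),
                 patient_id = ids, class = class),
            class = "si_training_set")
}

# --- metrics -----------------------------------------------------------------

f1_score <- function(pred, truth) {
  tp <- sum(pred == 1 & truth == 1)
  fp <- sum(pred == 1 & truth == 0)
  fn <- sum(pred == 0 & truth == 1)
  if (2 * tp + fp + fn == 0) return(0)
  2 * tp / (2 * tp + fp + fn)
}

# Rank-based ROC-AUC (equivalent to the Mann-Whitney statistic).
roc_auc <- function(scores, truth) {
  n1 <- sum(truth == 1); n0 <- sum(truth == 0)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(scores, ties.method = "average")
  (sum(r[truth == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# Average precision (step-wise area under the precision-recall curve).
pr_auc <- function(scores, truth) {
  n1 <- sum(truth == 1)
  if (n1 == 0) return(NA_real_)
  ord <- order(-scores)
  t <- truth[ord]
  prec <- cumsum(t) / seq_along(t)
  sum(prec[t == 1]) / n1
}

# --- model families ----------------------------------------------------------

fit_family <- function(family, x, y, nrounds = 50L) {
  if (family == "logistic") {
    df <- as.data.frame(x)
    df$.y <- y
    suppressWarnings(stats::glm(.y ~ ., data = df, family = stats::binomial()))
  } else {
    params <- list(objective = "binary:logistic", nthread = 1, eta = 0.3,
                   max_depth = 6)
    if (family == "xgb_dart") {
      params <- c(params, list(booster = "dart", rate_drop = 0.1,
                               skip_drop = 0.5))
    }
    dtrain <- xgboost::xgb.DMatrix(x, label = y, nthread = 1)
    xgboost::xgb.train(params = params, data = dtrain, nrounds = nrounds,
                       verbose = 0)
  }
}

predict_family <- function(family, fit, x) {
  if (family == "logistic") {
    suppressWarnings(unname(predict(fit, newdata = as.data.frame(x),
                                    type = "response")))
  } else {
    predict(fit, x)
  }
}

#' Train, compare and select classifier families by cross-validated F1
#'
#' Evaluates logistic regression and two gradient-boosted-tree variants
#' (xgboost `gbtree` and `dart` boosters) on identical stratified fold
#' assignments (4-fold by default), scoring each fold by F1 (at the 0.5
#' cutoff), ROC-AUC and the area under the precision-recall curve. The family
#' with the highest mean F1 wins (ties resolve to the first listed) and is
#' refit on the full training set. Out-of-fold predictions of the winning
#' family are pooled and retained for threshold tuning.
#'
#' @param ts An `si_training_set` from [make_training_set()], or a list with
#'   `x` and `y`.
#' @param seed Integer seed (fold assignment).
#' @param families Families to evaluate.
#' @param nfolds Number of folds (default 4).
#' @param nrounds Boosting rounds for the tree families (default 50).
#' @return An `si_model`: list `family`, `fit`, `feature_names`, `reports`
#'   (tibble: family, fold, f1, roc_auc, pr_auc, plus `selected` on the
#'   fold-mean rows with fold = NA), `oof` (tibble `score`, `label`).
#' @export
crossval_train <- function(ts, seed = 1L,
                           families = c("logistic", "xgb_tree", "xgb_dart"),
                           nfolds = 4L, nrounds = 50L) {
  x <- ts$x; y <- ts$y
  set.seed(seed)
  fold <- integer(length(y))
  for (cls in unique(y)) {
    idx <- which(y == cls)
    fold[idx] <- sample(rep_len(seq_len(nfolds), length(idx)))
  }
  assert_that(all(vapply(seq_len(nfolds), function(f)
    length(unique(y[fold == f])) == 2L, logical(1))),
    "stratification failed: a fold is missing one class")

  rows <- list(); oof <- list()
  for (fam in families) {
    scores <- numeric(length(y))
    for (f in seq_len(nfolds)) {
      tr <- fold != f
      fit <- fit_family(fam, x[tr, , drop = FALSE], y[tr], nrounds)
      scores[!tr] <- predict_family(fam, fit, x[!tr, , drop = FALSE])
      rows[[length(rows) + 1L]] <- tibble::tibble(
        family = fam, fold = f,
        f1 = f1_score(as.integer(scores[!tr] >= 0.5), y[!tr]),
        roc_auc = roc_auc(scores[!tr], y[!tr]),
        pr_auc = pr_auc(scores[!tr], y[!tr]))
    }
    oof[[fam]] <- scores
  }
  reports <- dplyr::bind_rows(rows)
  means <- reports |>
    dplyr::group_by(.data$family) |>
    dplyr::summarise(dplyr::across(c("f1", "roc_auc", "pr_auc"), mean),
                     .groups = "drop")
  means <- means[match(families, means$family), ]
  winner <- families[which.max(means$f1)]
  means$fold <- NA_integer_
  means$selected <- means$family == winner
  reports$selected <- NA
  reports <- dplyr::bind_rows(reports, means)

  final <- fit_family(winner, x, y, nrounds)
  structure(list(family = winner, fit = final,
                 feature_names = colnames(x), reports = reports,
                 oof = tibble::tibble(score = oof[[winner]], label = y),
                 nrounds = nrounds),
            class = "si_model")
}

#' @export
print.si_model <- function(x, ...) {
  m <- x$reports[is.na(x$reports$fold), ]
  cat(sprintf("<si_model> winner: %s (mean F1 %.3f, ROC-AUC %.3f, PR-AUC %.3f)\n",
              x$family, m$f1[m$selected], m$roc_auc[m$selected],
              m$pr_auc[m$selected]))
  invisible(x)
}

#' Predict intolerance scores with a trained calibration model
#'
#' @param model An `si_model` from [crossval_train()].
#' @param x Numeric matrix whose columns match the model's training features.
#' @return Numeric vector of scores in \[0, 1\].
#' @export
predict_si <- function(model, x) {
  assert_that(identical(colnames(x), model$feature_names),
              "feature names do not match the training matrix")
  predict_family(model$family, model$fit, x)
}

#' Tune the decision threshold to the precision-equals-recall point
#'
#' Sweeps candidate thresholds (the midpoints between consecutive unique
#' scores, plus one candidate below the minimum and one above the maximum) and
#' returns the one minimising |precision - recall|; ties resolve to the lowest
#' threshold. A threshold predicting no positives has precision 1 (no false
#' positives) and recall 0 by convention. At the precision-equals-recall point
#' false positives equal false negatives, so the predicted-positive count
#' matches the true-positive count.
#'
#' @param scores Numeric scores in \[0, 1\].
#' @param labels Binary labels (both classes present).
#' @return List `threshold`, `precision`, `recall`, `gap` (achieved |P - R|).
#' @export
find_threshold <- function(scores, labels) {
  assert_that(length(unique(labels)) == 2, "labels must contain both classes")
  u <- sort(unique(scores))
  candidates <- c(u[1] - 1e-9, if (length(u) > 1) (u[-1] + u[-length(u)]) / 2,
                  u[length(u)] + 1e-9)
  npos <- sum(labels == 1)
  best <- NULL
  for (t in candidates) {
    pred <- scores >= t
    tp <- sum(pred & labels == 1)
    p <- if (sum(pred) == 0) 1 else tp / sum(pred)
    r <- tp / npos
    gap <- abs(p - r)
    if (is.null(best) || gap < best$gap - 1e-12) {
      best <- list(threshold = t, precision = p, recall = r, gap = gap)
    }
  }
  best
}

#' Reclassify low-confidence patients
#'
#' Applies a trained high-confidence-versus-tolerant model to the feature rows
#' of the matching low-confidence class; a patient is predicted intolerant iff
#' their score is at or above the tuned threshold.
#'
#' @param model An `si_model`.
#' @param threshold Decision threshold from [find_threshold()].
#' @param x_low Feature rows (matrix, rownames = patient ids) of the
#'   low-confidence patients; columns must match the model's features.
#' @return Tibble `patient_id`, `score`, `predicted`
#'   (`"intolerant"`/`"tolerant"`); empty for an empty input.
#' @export
reclassify_low_confidence <- function(model, threshold, x_low) {
  if (nrow(x_low) == 0) {
    return(tibble::tibble(patient_id = character(), score = numeric(),
                          predicted = character()))
  }
  s <- predict_si(model, x_low)
  tibble::tibble(patient_id = rownames(x_low), score = s,
                 predicted = ifelse(s >= threshold, "intolerant", "tolerant"))
}

#' Update the prevalence table after reclassification
#'
#' Moves the predicted-intolerant low-confidence patients into the matching
#' high-confidence cell: high-after = high-before + predicted positives,
#' low-after = low-before - predicted positives. Tolerant, total and combined
#' SI counts are conserved; percentages are reported to one decimal
#' (half-up).
#'
#' @param rule_counts Named counts for `tolerant`, `absolute_high`,
#'   `absolute_low`, `partial_high`, `partial_low` (the rules-only stage).
#' @param n_reclass_absolute,n_reclass_partial Number of low-confidence
#'   patients predicted intolerant in each task.
#' @return Tibble `stage` (`rules_only` / `rules_plus_ml`), `label`, `count`,
#'   `pct`, covering `total` and the five labels.
#' @export
update_prevalence <- function(rule_counts, n_reclass_absolute = 0L,
                              n_reclass_partial = 0L) {
  labs <- si_labels()
  assert_that(all(labs %in% names(rule_counts)),
              "rule_counts must name all five labels")
  before <- as.numeric(rule_counts[labs])
  names(before) <- labs
  assert_that(n_reclass_absolute >= 0 && n_reclass_partial >= 0,
              "reclassification counts must be non-negative")
  assert_that(n_reclass_absolute <= before["absolute_low"],
              "more absolute reclassifications than low-confidence patients")
  assert_that(n_reclass_partial <= before["partial_low"],
              "more partial reclassifications than low-confidence patients")
  after <- before
  after["absolute_high"] <- before["absolute_high"] + n_reclass_absolute
  after["absolute_low"] <- before["absolute_low"] - n_reclass_absolute
  after["partial_high"] <- before["partial_high"] + n_reclass_partial
  after["partial_low"] <- before["partial_low"] - n_reclass_partial
  total <- sum(before)
  mk <- function(counts, stage) tibble::tibble(
    stage = stage,
    label = c("total", labs),
    count = c(total, unname(counts)),
    pct = round_half_up(100 * c(total, unname(counts)) / total, 1))
  dplyr::bind_rows(mk(before, "rules_only"), mk(after, "rules_plus_ml"))
}

#' Relative increase in high-confidence prevalence after calibration
#'
#' Computed from the one-decimal prevalence percentages of the table (the
#' convention of the published estimates): 100 * (after - before) / before.
#'
#' @param prevalence Output of [update_prevalence()].
#' @param class `"absolute"` or `"partial"`.
#' @return Percentage increase.
#' @export
prevalence_increase <- function(prevalence, class = c("absolute", "partial")) {
  class <- match.arg(class)
  lab <- paste0(class, "_high")
  before <- prevalence$pct[prevalence$stage == "rules_only" & prevalence$label == lab]
  after <- prevalence$pct[prevalence$stage == "rules_plus_ml" & prevalence$label == lab]
  100 * (after - before) / before
}

#' Feature attribution for a trained calibration model
#'
#' Tree families use their built-in Shapley-value attributions (mean absolute
#' SHAP per feature over the supplied rows); the logistic family uses
#' permutation importance (drop in ROC-AUC when one column is permuted), which
#' requires labels.
#'
#' @param model An `si_model`.
#' @param x Feature matrix sample (columns must match the model).
#' @param y Labels, required for the logistic family.
#' @param seed Seed for the permutations.
#' @return Tibble `feature`, `importance`, sorted descending.
#' @export
feature_importance <- function(model, x, y = NULL, seed = 1L) {
  assert_that(identical(colnames(x), model$feature_names),
              "feature names do not match the training matrix")
  if (model$family == "logistic") {
    assert_that(!is.null(y), "permutation importance needs labels")
    set.seed(seed)
    base <- roc_auc(predict_si(model, x), y)
    imp <- vapply(seq_len(ncol(x)), function(j) {
      xp <- x
      xp[, j] <- xp[sample.int(nrow(x)), j]
      base - roc_auc(predict_si(model, xp), y)
    }, numeric(1))
    imp <- pmax(imp, 0)
  } else {
    contrib <- predict(model$fit, x, predcontrib = TRUE)
    contrib <- contrib[, setdiff(colnames(contrib), c("BIAS", "(Intercept)")),
                       drop = FALSE]
    imp <- colMeans(abs(contrib))
  }
  out <- tibble::tibble(feature = colnames(x), importance = unname(imp))
  dplyr::arrange(out, dplyr::desc(.data$importance))
}

#' Run the full supervised calibration for both model tasks
#'
#' For each class (absolute, partial): build the training set, select features
#' by mutual information, train and compare the three families under
#' stratified 4-fold cross-validation, tune the threshold to the
#' precision-equals-recall point on the pooled out-of-fold predictions, and
#' reclassify that class's low-confidence patients. Finally update the
#' prevalence table.
#'
#' @param fm A `feature_matrix` from [build_features()].
#' @param classifications Classification tibble from [classify_cohort()].
#' @param n_tolerant Tolerant sample size per task (default 50000).
#' @param k_features Mutual-information selection size (default 400, capped
#'   at the number of columns).
#' @param seed Integer seed.
#' @param families,nrounds Passed to [crossval_train()].
#' @return An `si_calibration`: list `models`, `thresholds`, `selected_features`,
#'   `reclassified` (tibble `patient_id`, `task`, `score`, `predicted`),
#'   `prevalence` (both stages), `rule_counts`.
#' @export
calibrate_si <- function(fm, classifications, n_tolerant = 50000L,
                         k_features = 400L, seed = 1L,
                         families = c("logistic", "xgb_tree", "xgb_dart"),
                         nrounds = 50L) {
  x <- fm$x
  counts <- table(classifications$label)
  rule_counts <- setNames(as.integer(counts[si_labels()]), si_labels())
  rule_counts[is.na(rule_counts)] <- 0L

  models <- list(); thresholds <- list(); sel_feats <- list()
  reclass <- list(); n_pos <- c(absolute = 0L, partial = 0L)
  for (task in c("absolute", "partial")) {
    task_seed <- seed + match(task, c("absolute", "partial")) - 1L
    ts <- make_training_set(fm, classifications, task, n_tolerant, task_seed)
    sel <- select_features(ts$x, ts$y, k_features)
    keep <- sel$selected[order(match(sel$selected, colnames(ts$x)))]
    model <- crossval_train(list(x = ts$x[, keep, drop = FALSE], y = ts$y),
                            seed = task_seed, families = families,
                            nrounds = nrounds)
    thr <- find_threshold(model$oof$score, model$oof$label)
    low_ids <- classifications$patient_id[
      classifications$label == paste0(task, "_low")]
    rc <- reclassify_low_confidence(model, thr$threshold,
                                    x[low_ids, keep, drop = FALSE])
    rc$task <- task
    models[[task]] <- model
    thresholds[[task]] <- thr
    sel_feats[[task]] <- keep
    reclass[[task]] <- rc
    n_pos[task] <- sum(rc$predicted == "intolerant")
  }
  prevalence <- update_prevalence(rule_counts, n_pos[["absolute"]],
                                  n_pos[["partial"]])
  structure(list(models = models, thresholds = thresholds,
                 selected_features = sel_feats,
                 reclassified = dplyr::bind_rows(reclass),
                 prevalence = prevalence, rule_counts = rule_counts),
            class = "si_calibration")
}
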