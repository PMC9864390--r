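#' Build the patient-level feature matrix
#'
#' One row per cohort entry, built from events inside each patient's
#' `[lookback_start, study_end)` window: presence and count per 3-character
#' ICD-10 group, presence and count per level-4 ATC class, demographics (age
#' at index, one-hot gender) and utilisation features (total prescriptions,
#' distinct molecules, distinct ATC level-4 classes, distinct lipid-lowering
#' molecules, and distinct event dates as a proxy for physician visits).
#' Absence is encoded 0; there are no missing values.
#'
#' @param cohort An [emr_cohort()].
#' @param entries Entries tibble from [select_cohort()].
#' @param config A [study_config()].
#' @return A `feature_matrix`: list with `x` (numeric matrix, patients x
#'   features, rownames = patient ids), `feature_kinds` (named character
#'   vector: `presence`, `frequency`, `demographic` or `utilization`).
#' @export
build_features <- function(cohort, entries, config = study_config()) {
  ids <- entries$patient_id
  win <- entries[c("patient_id", "lookback_start")]

  dg <- dplyr::inner_join(cohort$diagnoses, win, by = "patient_id")
  dg <- dplyr::filter(dg, .data$date >= .data$lookback_start,
                      .data$date < config$study_end)
  dg$group <- substr(dg$icd10, 1, 3)

  rx <- dplyr::inner_join(cohort$prescriptions, win, by = "patient_id")
  rx <- dplyr::filter(rx, .data$date >= .data$lookback_start,
                      .data$date < config$study_end)
  rx$group <- substr(rx$atc, 1, 5)

  blocks <- list()
  wide_counts <- function(df, prefix) {
    counts <- dplyr::count(df, .data$patient_id, .data$group, name = "n")
    groups <- sort(unique(counts$group))
    m <- matrix(0, length(ids), length(groups),
                dimnames = list(ids, paste0(prefix, groups, "_count")))
    if (nrow(counts)) {
      m[cbind(match(counts$patient_id, ids), match(counts$group, groups))] <- counts$n
    }
    m
  }
  if (nrow(dg)) {
    cnt <- wide_counts(dg, "icd_")
    pres <- (cnt > 0) + 0
    colnames(pres) <- sub("_count$", "_present", colnames(cnt))
    blocks$icd <- cbind(pres, cnt)
  }
  if (nrow(rx)) {
    cnt <- wide_counts(rx, "atc_")
    pres <- (cnt > 0) + 0
    colnames(pres) <- sub("_count$", "_present", colnames(cnt))
    blocks$atc <- cbind(pres, cnt)
  }

  pats <- cohort$patients[match(ids, cohort$patients$patient_id), ]
  demo <- cbind(age_at_index = entries$age_at_index,
                gender_female = (pats$gender == "female") + 0,
                gender_male = (pats$gender == "male") + 0,
                gender_unspecified = (pats$gender == "unspecified") + 0)
  rownames(demo) <- ids

  is_llt <- matches_prefix(rx$atc, config$atc_sets$llt)
  util_rx <- rx |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::summarise(n_prescriptions = dplyr::n(),
                     n_molecules = dplyr::n_distinct(.data$molecule),
                     n_atc_classes = dplyr::n_distinct(.data$group),
                     .groups = "drop")
  util_llt <- rx[is_llt, ] |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::summarise(n_llt_molecules = dplyr::n_distinct(.data$molecule),
                     .groups = "drop")
  visits <- dplyr::bind_rows(dg[c("patient_id", "date")],
                             rx[c("patient_id", "date")]) |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::summarise(n_visit_days = dplyr::n_distinct(.data$date),
                     .groups = "drop")
  util <- matrix(0, length(ids), 5,
                 dimnames = list(ids, c("n_prescriptions", "n_molecules",
                                        "n_atc_classes", "n_llt_molecules",
                                        "n_visit_days")))
  fill <- function(df, col) {
    if (nrow(df)) util[match(df$patient_id, ids), col] <<- df[[col]]
  }
  fill(util_rx, "n_prescriptions"); fill(util_rx, "n_molecules")
  fill(util_rx, "n_atc_classes"); fill(util_llt, "n_llt_molecules")
  fill(visits, "n_visit_days")

  x <- do.call(cbind, c(unname(blocks), list(demo, util)))
  kinds <- setNames(
    dplyr::case_when(grepl("_present$", colnames(x)) ~ "presence",
                     grepl("_count$", colnames(x)) ~ "frequency",
                     colnames(x) %in% colnames(demo) ~ "demographic",
                     TRUE ~ "utilization"),
    colnames(x))
  assert_that(!anyDuplicated(colnames(x)), "duplicate feature names")
  structure(list(x = x, feature_kinds = kinds), class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix> %d patients x %d features\n",
              nrow(x$x), ncol(x$x)))
  invisible(x)
}

#' Mutual information between one feature and a discrete target
#'
#' Estimates I(X; Y) in nats between a numeric feature and a discrete (binary)
#' target. Features with at most `discrete_threshold` distinct values use the
#' plug-in estimator on the joint contingency table; continuous features use
#' the k-nearest-neighbour entropy estimator for a continuous variable against
#' a discrete one (the Kozachenko-Leonenko construction in its
#' mixed-variable form): with d_i the distance from point i to its k-th
#' neighbour within the same class and m_i the number of points of any class
#' strictly within d_i,
#' `I = psi(N) + psi(k) - mean(psi(n_class)) - mean(psi(m))`.
#' Estimates are clipped at zero.
#'
#' @param feature Numeric vector.
#' @param target Vector with at least two distinct values (the class label).
#' @param k_neighbors Neighbour count for the continuous estimator (default 3).
#' @param discrete_threshold Maximum cardinality treated as discrete
#'   (default 20).
#' @return Non-negative scalar, nats.
#' @export
mutual_information <- function(feature, target, k_neighbors = 3L,
                               discrete_threshold = 20L) {
  assert_that(length(feature) == length(target), "vectors must match in length")
  assert_that(length(feature) >= 10, "need at least 10 observations")
  assert_that(length(unique(target)) >= 2,
              "mutual information is undefined for a constant target")
  if (length(unique(feature)) <= discrete_threshold) {
    return(mi_discrete(feature, target))
  }
  mi_knn_mixed(feature, target, k_neighbors)
}

# Plug-in MI on the joint contingency table, in nats.
mi_discrete <- function(x, y) {
  tab <- table(x, y)
  n <- sum(tab)
  pxy <- tab / n
  px <- rowSums(pxy); py <- colSums(pxy)
  nz <- pxy > 0
  mi <- sum(pxy[nz] * log(pxy[nz] / outer(px, py)[nz]))
  max(mi, 0)
}

# k-NN estimator for continuous x vs discrete y (1-D, O(n log n)).
mi_knn_mixed <- function(x, y, k = 3L) {
  n <- length(x)
  ord <- order(x)
  xs <- x[ord]; ys <- y[ord]
  k_used <- numeric(n); m <- numeric(n)
  classes <- unique(ys)
  n_class <- setNames(tabulate(match(ys, classes)), classes)
  pos_all <- seq_len(n)
  for (cl in classes) {
    idx <- which(ys == cl)          # positions in sorted order, ascending
    v <- xs[idx]
    nc <- length(v)
    if (nc < 2) { k_used[idx] <- NA; m[idx] <- NA; next }
    kk <- min(k, nc - 1L)
    # distance to kk-th nearest neighbour within the class (sorted 1-D)
    d <- vapply(seq_len(nc), function(j) {
      lo <- max(1L, j - kk); hi <- min(nc, j + kk)
      sort(abs(v[lo:hi] - v[j]))[kk + 1L]
    }, numeric(1))
    # count of all points strictly within that radius (self included)
    r <- d * (1 - 1e-10)
    cnt <- findInterval(v + r, xs) - findInterval(v - r - 1e-300, xs)
    k_used[idx] <- kk
    m[idx] <- cnt
  }
  keep <- !is.na(m) & m > 0
  mi <- digamma(n) + mean(digamma(k_used[keep])) -
    mean(digamma(n_class[as.character(ys[keep])])) -
    mean(digamma(m[keep]))
  max(mi, 0)
}

#' Select the top-k features by mutual information
#'
#' Scores every column of the feature matrix against a binary target with
#' [mutual_information()] and keeps the `k` highest-scoring columns. Ties are
#' broken by column order, so selection is deterministic.
#'
#' @param fm A `feature_matrix` from [build_features()], or a plain numeric
#'   matrix with column names.
#' @param labels Binary vector (intolerant vs tolerant), one per row.
#' @param k Number of features to keep (default 400, capped at the number of
#'   columns).
#' @param k_neighbors Passed to [mutual_information()].
#' @return List with `scores` (named numeric, all features, original column
#'   order) and `selected` (character, descending score).
#' @export
select_features <- function(fm, labels, k = 400L, k_neighbors = 3L) {
  assert_that(k > 0, "k must be positive")
  x <- if (inherits(fm, "feature_matrix")) fm$x else fm
  assert_that(nrow(x) == length(labels), "labels must match matrix rows")
  scores <- apply(x, 2, mutual_information, target = labels,
                  k_neighbors = k_neighbors)
  ord <- order(-scores, seq_along(scores))
  selected <- colnames(x)[ord][seq_len(min(k, ncol(x)))]
  list(scores = scores, selected = selected, k = as.integer(k))
}
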