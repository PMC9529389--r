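#' Confusion matrix for nodule / nonnodule classification
#'
#' The positive class is the nodule (+1): `tp` counts nodules detected as
#' nodules, `tn` nonnodules detected as nonnodules, `fp` nonnodules called
#' nodules, `fn` missed nodules.
#'
#' @param pred_labels hard predictions in \{-1, +1\}.
#' @param true_labels true labels in \{-1, +1\}.
#' @return An object of class `confusion_matrix`: list with `tp`, `tn`,
#'   `fp`, `fn`.
#' @export
confusion <- function(pred_labels, true_labels) {
  if (length(pred_labels) != length(true_labels))
    stopf("pred_labels (%d) and true_labels (%d) must have equal length",
          length(pred_labels), length(true_labels))
  structure(list(
    tp = sum(pred_labels > 0 & true_labels > 0),
    tn = sum(pred_labels < 0 & true_labels < 0),
    fp = sum(pred_labels > 0 & true_labels < 0),
    fn = sum(pred_labels < 0 & true_labels > 0)
  ), class = "confusion_matrix")
}

#' Accuracy, sensitivity and specificity
#'
#' `accuracy = (tp + tn) / (tp + tn + fp + fn)`,
#' `sensitivity = tp / (tp + fn)` (recall on nodules),
#' `specificity = tn / (tn + fp)` (recall on nonnodules).
#' A metric whose denominator is zero is undefined and raises an error
#' rather than silently returning 0, since silent zeros would corrupt
#' cross-validation averages.
#'
#' @param cm a [confusion()] result.
#' @return List with `accuracy`, `sensitivity`, `specificity`.
#' @export
metrics <- function(cm) {
  total <- cm$tp + cm$tn + cm$fp + cm$fn
  if (total == 0) stopf("metrics undefined: empty evaluation (all counts zero)")
  if (cm$tp + cm$fn == 0)
    stopf("sensitivity undefined: no positive-class samples (tp + fn = 0)")
  if (cm$tn + cm$fp == 0)
    stopf("specificity undefined: no negative-class samples (tn + fp = 0)")
  list(accuracy = (cm$tp + cm$tn) / total,
       sensitivity = cm$tp / (cm$tp + cm$fn),
       specificity = cm$tn / (cm$tn + cm$fp))
}

#' ROC curve and AUC from continuous scores
#'
#' Sweeps the decision threshold over the unique scores in descending order
#' (samples scoring at least the threshold are called positive; tied scores
#' are grouped, one operating point per unique score), computes
#' `TPR = tp / (tp + fn)` and `FPR = fp / (tn + fp)` at each point, anchors
#' the curve at (0, 0) and (1, 1), and integrates by the trapezoid rule.
#'
#' @param margin_scores continuous scores, larger meaning more nodule-like
#'   (e.g. ensemble margins or probabilities).
#' @param true_labels labels in \{-1, +1\}; both classes must be present.
#' @return An object of class `roc_curve`: list with `points` (data frame
#'   `fpr`, `tpr`, `threshold`) and `auc`.
#' @export
roc <- function(margin_scores, true_labels) {
  if (length(margin_scores) != length(true_labels))
    stopf("scores and labels must have equal length")
  P <- sum(true_labels > 0)
  N <- sum(true_labels < 0)
  if (P == 0 || N == 0) stopf("ROC undefined: both classes must be present")
  ord <- order(margin_scores, decreasing = TRUE)
  s <- margin_scores[ord]
  y <- true_labels[ord]
  grp_last <- c(which(diff(s) != 0), length(s))  # last index of each tie group
  ctp <- cumsum(y > 0)
  cfp <- cumsum(y < 0)
  tpr <- c(0, ctp[grp_last] / P, 1)
  fpr <- c(0, cfp[grp_last] / N, 1)
  thr <- c(Inf, s[grp_last], -Inf)
  keep <- !duplicated(cbind(fpr, tpr))
  pts <- data.frame(fpr = fpr[keep], tpr = tpr[keep], threshold = thr[keep])
  auc <- sum(diff(pts$fpr) * (pts$tpr[-1] + pts$tpr[-nrow(pts)]) / 2)
  structure(list(points = pts, auc = auc), class = "roc_curve")
}

#' Stratified 80/20 train/test split
#'
#' Splits candidate ids into train and test sets, stratified by label, with
#' `round(test_frac * n)` total test samples apportioned across classes by
#' largest remainder. Deterministic per seed. A class with fewer than 2
#' members triggers a warning and an unstratified split.
#'
#' @param candidates candidate data frame with `candidate_id` and `label`
#'   columns.
#' @param seed integer seed.
#' @param test_frac test fraction, default 0.2.
#' @return List with `train` and `test` character vectors of candidate ids
#'   (disjoint, exhaustive).
#' @export
split_80_20 <- function(candidates, seed = 1L, test_frac = 0.2) {
  n <- nrow(candidates)
  if (n < 5L) stopf("need at least 5 samples to split, got %d", n)
  ids <- as.character(candidates$candidate_id)
  lab <- candidates$label
  n_test <- round(test_frac * n)
  with_seed(derive_seed(seed, 29L), {
    if (min(table(lab)) < 2L) {
      warning("a class has fewer than 2 members; falling back to unstratified split",
              call. = FALSE)
      test <- sample(ids, n_test)
    } else {
      classes <- sort(unique(lab))
      quota <- test_frac * tabulate(match(lab, classes))
      base <- floor(quota)
      rem <- quota - base
      extra <- n_test - sum(base)
      if (extra > 0) base[order(rem, decreasing = TRUE)[seq_len(extra)]] <-
          base[order(rem, decreasing = TRUE)[seq_len(extra)]] + 1
      test <- unlist(lapply(seq_along(classes), function(k)
        sample(ids[lab == classes[k]], base[k])))
    }
    list(train = setdiff(ids, test), test = sort(test))
  })
}

# stratified fold assignment: shuffle within each class, concatenate the
# classes, then deal the whole sequence round-robin with one running
# pointer. Each class is split as evenly as possible across folds and
# total fold sizes differ by at most one.
stratified_folds <- function(labels, k, seed) {
  n <- length(labels)
  folds <- integer(n)
  with_seed(derive_seed(seed, 31L), {
    ordered <- unlist(lapply(sort(unique(labels)), function(cl)
      sample(which(labels == cl))))
    folds[ordered] <- rep_len(seq_len(k), n)
  })
  folds
}

#' Stratified k-fold cross-validation
#'
#' Deals samples into `k` stratified folds; each fold serves as the test set
#' exactly once while the remainder trains. Reports per-fold accuracy,
#' sensitivity, specificity and AUC, plus their means.
#'
#' @param labels vector of +1/-1 labels.
#' @param fit_predict function `(train_idx, test_idx) -> list(scores,
#'   labels)` returning continuous scores and hard +1/-1 predictions for the
#'   test indices after training on the train indices.
#' @param k number of folds, default 10.
#' @param seed integer seed for the fold assignment.
#' @return List with `per_fold` (data frame) and `mean` (named list).
#' @export
cross_validate <- function(labels, fit_predict, k = 10L, seed = 1L) {
  n <- length(labels)
  if (n < k) stopf("need at least k = %d samples for %d-fold CV, got %d; reduce k",
                   k, k, n)
  if (min(table(labels)) < k)
    stopf("smallest class has fewer than k = %d members; reduce k", k)
  folds <- stratified_folds(labels, k, seed)
  rows <- lapply(seq_len(k), function(f) {
    test_idx <- which(folds == f)
    train_idx <- which(folds != f)
    res <- fit_predict(train_idx, test_idx)
    m <- metrics(confusion(res$labels, labels[test_idx]))
    auc <- roc(res$scores, labels[test_idx])$auc
    data.frame(fold = f, accuracy = m$accuracy, sensitivity = m$sensitivity,
               specificity = m$specificity, auc = auc)
  })
  per_fold <- do.call(rbind, rows)
  list(per_fold = per_fold,
       mean = as.list(colMeans(per_fold[, -1])))
}
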