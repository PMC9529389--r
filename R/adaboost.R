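#' AdaBoost weight machinery
#'
#' The boosting engine is base-learner agnostic: any object with a
#' `fit(x, y, w, seed)` function returning a model and a `predict(model, x)`
#' function returning hard labels in \{-1, +1\} can be boosted. Labels are
#' +1 (nodule) / -1 (nonnodule) internally, which the multiplicative weight
#' update `S_{m+1}(i) = S_m(i) exp(-d_m c_i f_m(x_i)) / Z_m` requires.
#'
#' @name adaboost
NULL

#' Uniform initial sample weights
#'
#' @param n sample count, at least 1.
#' @return Numeric vector of `n` entries `1/n`.
#' @export
init_weights <- function(n) {
  if (!is_count(n) || n < 1) stopf("n must be a positive count")
  rep(1 / n, n)
}

check_weights <- function(weights, n = length(weights)) {
  if (length(weights) != n) stopf("weight vector length mismatch")
  if (any(weights < 0)) stopf("sample weights must be nonnegative")
  if (abs(sum(weights) - 1) > 1e-8) stopf("sample weights must sum to 1")
  invisible(weights)
}

#' Weighted training error of a round
#'
#' Sum of sample weights over misclassified samples.
#'
#' @param predictions hard labels in \{-1, +1\}.
#' @param labels true labels in \{-1, +1\}.
#' @param weights probability vector of sample weights.
#' @return The weighted error in `[0, 1]`.
#' @export
weighted_error <- function(predictions, labels, weights) {
  if (length(predictions) != length(labels) || length(labels) != length(weights))
    stopf("predictions (%d), labels (%d) and weights (%d) must have equal length",
          length(predictions), length(labels), length(weights))
  sum(weights[predictions != labels])
}

#' Voting weight of a base learner
#'
#' `d = 0.5 * log((1 - eps) / eps)`, positive iff the round beats chance.
#' `eps` is clamped symmetrically into `[1e-10, 1 - 1e-10]` first so the
#' vote stays finite when a learner is perfect (or perfectly wrong) on the
#' weighted sample.
#'
#' @param epsilon weighted error.
#' @param clamp clamping bound.
#' @return The voting weight (log-odds scale).
#' @export
voting_weight <- function(epsilon, clamp = 1e-10) {
  eps <- min(max(epsilon, clamp), 1 - clamp)
  0.5 * log((1 - eps) / eps)
}

#' Multiplicative sample-weight update
#'
#' Each weight is multiplied by `exp(-d * c_i * f_i)` and the vector is
#' renormalized by `Z = sum` of the unnormalized weights: correctly
#' classified samples (where `c_i * f_i = +1`) shrink and misclassified
#' samples grow, directing the next learner's attention to past errors.
#'
#' @param weights current probability vector.
#' @param d voting weight of the round just trained.
#' @param labels true labels, +1/-1.
#' @param predictions the round's hard predictions, +1/-1.
#' @return List with `weights` (updated probability vector) and `Z` (the
#'   normalizer).
#' @export
update_weights <- function(weights, d, labels, predictions) {
  check_weights(weights)
  if (length(labels) != length(weights) || length(predictions) != length(weights))
    stopf("labels/predictions length must match weights")
  un <- weights * exp(-d * labels * predictions)
  Z <- sum(un)
  stopifnot(Z > 0)
  list(weights = un / Z, Z = Z)
}

#' Fit an AdaBoost ensemble
#'
#' Runs `M` rounds of: train a base learner under the current sample
#' weights, take its hard predictions on the training set, compute the
#' weighted error and the voting weight, and update the weights. Each
#' round's learner seed is derived deterministically from `seed`.
#'
#' A round with weighted error >= 0.5 triggers `epsilon_policy`:
#' `"continue"` (default) keeps the round with its non-positive vote and
#' carries on for the fixed number of rounds; `"stop"` ends boosting at that
#' round (the round is kept, so the ensemble is never empty).
#'
#' @param x training inputs, passed opaquely to the base learner.
#' @param labels vector of +1/-1 labels.
#' @param M number of boosting rounds, >= 1.
#' @param learner list with functions `fit(x, y, w, seed) -> model` and
#'   `predict(model, x) -> hard labels`; see [stump_learner()] and
#'   [cnn_learner()].
#' @param seed master seed for the per-round learner seeds.
#' @param voting `"weighted"` (votes `d_m`) or `"simple"` (majority).
#' @param epsilon_policy `"continue"` or `"stop"`.
#' @return An object of class `ada_ensemble`: list with `rounds` (each
#'   holding `m`, `epsilon`, `d`, `Z`, `model`, `train_predictions`),
#'   `voting`, and the training-error bound trace `bound` (cumulative
#'   product of `2 * sqrt(eps_m (1 - eps_m))`).
#' @export
fit_ensemble <- function(x, labels, M, learner, seed = 1L,
                         voting = c("weighted", "simple"),
                         epsilon_policy = c("continue", "stop")) {
  voting <- match.arg(voting)
  epsilon_policy <- match.arg(epsilon_policy)
  if (!is_count(M) || M < 1) stopf("M must be a positive count")
  labels <- as.numeric(labels)
  if (!all(labels %in% c(-1, 1))) stopf("labels must be +1/-1")
  if (length(unique(labels)) < 2L) stopf("both classes must be present")
  n <- length(labels)
  S <- init_weights(n)
  rounds <- list()
  bound <- numeric(0)
  prod_bound <- 1
  for (m in seq_len(M)) {
    mseed <- derive_seed(seed, m)
    model <- learner$fit(x, labels, S, mseed)
    preds <- as.numeric(learner$predict(model, x))
    eps_raw <- weighted_error(preds, labels, S)
    eps <- min(max(eps_raw, 1e-10), 1 - 1e-10)
    d <- voting_weight(eps_raw)
    if (eps_raw >= 0.5)
      warning(sprintf("round %d weighted error %.3f >= 0.5 (policy: %s)",
                      m, eps_raw, epsilon_policy), call. = FALSE)
    upd <- update_weights(S, d, labels, preds)
    prod_bound <- prod_bound * 2 * sqrt(eps * (1 - eps))
    bound <- c(bound, prod_bound)
    rounds[[m]] <- list(m = m, epsilon = eps, d = d, Z = upd$Z,
                        seed = mseed, model = model,
                        train_predictions = preds)
    S <- upd$weights
    if (eps_raw >= 0.5 && epsilon_policy == "stop") break
  }
  structure(list(rounds = rounds, voting = voting, learner = learner,
                 final_weights = S, bound = bound),
            class = "ada_ensemble")
}

#' Ensemble prediction by weighted or simple voting
#'
#' The margin is `sum_m d_m f_m(x)` under weighted voting (each `f_m(x)` a
#' hard +1/-1 prediction) or the unweighted sum of hard predictions under
#' simple voting. The hard label is the sign of the margin, with a margin of
#' exactly 0 mapped to +1. The margin doubles as the continuous score for
#' ROC analysis.
#'
#' @param ensemble an `ada_ensemble`.
#' @param x inputs in the base learner's format.
#' @return List with `label` (+1/-1 vector) and `margin` (numeric vector).
#' @export
predict_ensemble <- function(ensemble, x) {
  if (!inherits(ensemble, "ada_ensemble") || length(ensemble$rounds) == 0L)
    stopf("ensemble must be a fitted ada_ensemble with at least one round")
  margins <- NULL
  for (r in ensemble$rounds) {
    f <- as.numeric(ensemble$learner$predict(r$model, x))
    contrib <- if (ensemble$voting == "weighted") r$d * f else f
    margins <- if (is.null(margins)) contrib else margins + contrib
  }
  list(label = ifelse(margins >= 0, 1L, -1L), margin = margins)
}

#' Ensemble training error and the AdaBoost bound
#'
#' @param ensemble an `ada_ensemble`.
#' @param x training inputs.
#' @param labels training labels +1/-1.
#' @return List with `error` (misclassification rate of the weighted vote)
#'   and `bound` (`prod_m 2 sqrt(eps_m (1 - eps_m))`).
#' @export
training_error <- function(ensemble, x, labels) {
  pe <- predict_ensemble(ensemble, x)
  list(error = mean(pe$label != labels),
       bound = ensemble$bound[length(ensemble$bound)])
}
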