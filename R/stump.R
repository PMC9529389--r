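#' Decision-stump base learner
#'
#' A weighted decision stump over the columns of a numeric matrix: predicts
#' `polarity` if `x[, feature] > threshold` and `-polarity` otherwise,
#' choosing the (feature, threshold, polarity) triple that minimizes the
#' weighted training error by exhaustive search over midpoints of sorted
#' feature values (plus one threshold below all values). Ties are broken by
#' scan order, so fitting is deterministic and independent of the seed.
#'
#' Stumps exist in the package so the boosting machinery can be exercised
#' and verified exactly, free of the stochasticity of network training; they
#' are also the classic weak learner for which boosting's behavior is well
#' understood.
#'
#' @return A learner interface (list with `fit` and `predict`) accepted by
#'   [fit_ensemble()]. `x` must be a numeric matrix (rows = samples).
#' @examples
#' x <- matrix(c(1, 2, 3, 4, 5, 6, 7, 8), ncol = 1)
#' y <- c(1, 1, 1, -1, -1, -1, 1, 1)
#' ens <- fit_ensemble(x, y, M = 5, learner = stump_learner())
#' training_error(ens, x, y)$error
#' @export
stump_learner <- function() {
  fit <- function(x, y, w, seed) {
    if (!is.matrix(x)) x <- as.matrix(x)
    best <- list(err = Inf, feature = 1L, threshold = -Inf, polarity = 1)
    for (jf in seq_len(ncol(x))) {
      v <- x[, jf]
      sv <- sort(unique(v))
      thr <- c(sv[1] - 1, if (length(sv) > 1) (sv[-1] + sv[-length(sv)]) / 2)
      for (t in thr) {
        pred <- ifelse(v > t, 1, -1)
        for (pol in c(1, -1)) {
          err <- sum(w[pol * pred != y])
          if (err < best$err - 1e-15) {
            best <- list(err = err, feature = jf, threshold = t, polarity = pol)
          }
        }
      }
    }
    best
  }
  predict <- function(model, x) {
    if (!is.matrix(x)) x <- as.matrix(x)
    model$polarity * ifelse(x[, model$feature] > model$threshold, 1, -1)
  }
  list(fit = fit, predict = predict, type = "stump")
}

#' CNN base-learner adapter for boosting
#'
#' Wraps the self-normalizing multiview CNN as a [fit_ensemble()] base
#' learner: `fit` builds and trains a fresh network (seeded per round) under
#' the current sample weights; `predict` thresholds [predict_score()] at 0.5.
#' `x` is a list of `multiview_patch` objects.
#'
#' @param spec a [base_learner_spec()].
#' @return A learner interface (list with `fit` and `predict`).
#' @export
cnn_learner <- function(spec) {
  fit <- function(x, y, w, seed) {
    sp <- spec
    sp$seed <- as.integer(seed %% 2147483647)
    lrn <- build_base_learner(sp)
    train_base_learner(lrn, x, sample_weights = w)
  }
  predict <- function(model, x) score_to_label(predict_score(model, x))
  list(fit = fit, predict = predict, type = "snmv_cnn", spec = spec)
}
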