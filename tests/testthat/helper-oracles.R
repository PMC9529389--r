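# Independent oracles used by the tests. These deliberately re-derive the
# quantities with naive, loop-heavy code so they share nothing with the
# package implementation beyond the documented conventions.

# SELU by direct evaluation of the closed form
oracle_selu <- function(x, alpha = 1.6733, lambda = 1.0507) {
  vapply(x, function(v) {
    if (v > 0) lambda * v else lambda * alpha * (exp(v) - 1)
  }, numeric(1))
}

# AUC as the pairwise Mann-Whitney statistic:
# P(score_pos > score_neg) + 0.5 * P(tie), by brute force over all pairs
oracle_auc <- function(scores, labels) {
  pos <- scores[labels > 0]
  neg <- scores[labels < 0]
  total <- 0
  for (p in pos) for (q in neg) {
    total <- total + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  total / (length(pos) * length(neg))
}

# Weighted decision stump by exhaustive search. Same documented tie-break
# (first strict improvement in scan order: features, ascending midpoints,
# polarity +1 before -1) but independently coded.
oracle_stump_fit <- function(X, y, w) {
  best_err <- Inf
  best <- NULL
  for (jf in seq_len(ncol(X))) {
    v <- X[, jf]
    sv <- sort(unique(v))
    thr <- sv[1] - 1
    if (length(sv) > 1) {
      for (i in 2:length(sv)) thr <- c(thr, (sv[i - 1] + sv[i]) / 2)
    }
    for (t in thr) {
      for (pol in c(1, -1)) {
        pred <- rep(-pol, length(v))
        pred[v > t] <- pol
        err <- 0
        for (i in seq_along(v)) if (pred[i] != y[i]) err <- err + w[i]
        if (err < best_err - 1e-15) {
          best_err <- err
          best <- list(feature = jf, threshold = t, polarity = pol)
        }
      }
    }
  }
  best
}

oracle_stump_predict <- function(model, X) {
  v <- X[, model$feature]
  pred <- rep(-model$polarity, length(v))
  pred[v > model$threshold] <- model$polarity
  pred
}

# Naive AdaBoost transcript with stump base learners: records eps, d and the
# full weight vector of every round.
oracle_adaboost <- function(X, y, M) {
  n <- length(y)
  S <- rep(1 / n, n)
  eps <- numeric(M)
  d <- numeric(M)
  W <- matrix(0, nrow = M + 1, ncol = n)
  W[1, ] <- S
  models <- vector("list", M)
  for (m in seq_len(M)) {
    models[[m]] <- oracle_stump_fit(X, y, S)
    pred <- oracle_stump_predict(models[[m]], X)
    e <- 0
    for (i in seq_len(n)) if (pred[i] != y[i]) e <- e + S[i]
    eps[m] <- e
    ec <- min(max(e, 1e-10), 1 - 1e-10)
    d[m] <- 0.5 * log((1 - ec) / ec)
    un <- S * exp(-d[m] * y * pred)
    S <- un / sum(un)
    W[m + 1, ] <- S
  }
  list(eps = eps, d = d, weights = W, models = models)
}

# Exhaustive search for the best single stump's unweighted error rate
oracle_best_stump_error <- function(X, y) {
  w <- rep(1 / length(y), length(y))
  m <- oracle_stump_fit(X, y, w)
  mean(oracle_stump_predict(m, X) != y)
}

# Bilinear interpolation of a square patch onto a target grid under the
# align-corners convention (output index i samples i * (n-1) / (t-1))
oracle_bilinear_resize <- function(patch, target) {
  n <- nrow(patch)
  out <- matrix(0, target, target)
  for (i in seq_len(target)) {
    for (j in seq_len(target)) {
      u <- (i - 1) * (n - 1) / (target - 1)
      v <- (j - 1) * (n - 1) / (target - 1)
      i0 <- min(floor(u), n - 2); i1 <- i0 + 1
      j0 <- min(floor(v), n - 2); j1 <- j0 + 1
      fu <- u - i0; fv <- v - j0
      out[i, j] <- (1 - fu) * (1 - fv) * patch[i0 + 1, j0 + 1] +
        fu * (1 - fv) * patch[i1 + 1, j0 + 1] +
        (1 - fu) * fv * patch[i0 + 1, j1 + 1] +
        fu * fv * patch[i1 + 1, j1 + 1]
    }
  }
  out
}

# Small synthetic multiview patch set: class +1 carries a bright Gaussian
# center template, class -1 plain noise. Linearly separable at amp >> sd.
make_toy_patches <- function(n, size = 12L, n_views = 2L, amp = 2, seed = 1) {
  stopifnot(n %% 2 == 0)
  set.seed(seed)
  ctr <- (size + 1) / 2
  d2 <- outer((seq_len(size) - ctr)^2, (seq_len(size) - ctr)^2, `+`)
  template <- exp(-d2 / (2 * (size / 6)^2))
  lapply(seq_len(n), function(i) {
    lab <- if (i <= n / 2) 1L else -1L
    views <- array(rnorm(size * size * n_views, sd = 1),
                   dim = c(size, size, n_views))
    if (lab > 0) for (v in seq_len(n_views)) views[, , v] <- views[, , v] + amp * template
    structure(list(views = views, label = lab,
                   candidate_id = sprintf("toy-%03d", i)),
              class = "multiview_patch")
  })
}

# Fast phantom configuration for tests that only need plumbing, not the
# full-size study conditions.
tiny_phantom_config <- function(seed = 1L, n_nodules = 6L, n_nonnodules = 6L) {
  phantom_config(volume_shape = c(40L, 72L, 72L),
                 n_nodules = n_nodules, n_nonnodules = n_nonnodules,
                 nodule_diameter_range = c(5, 9), vessel_count = 6L,
                 min_separation = 14, seed = seed)
}
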