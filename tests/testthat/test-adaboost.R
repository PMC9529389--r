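test_that("initial weights are uniform and normalized", {
  expect_equal(init_weights(4), rep(0.25, 4))
  expect_equal(init_weights(1), 1)
  for (n in c(3, 7, 100)) expect_lt(abs(sum(init_weights(n)) - 1), 1e-12)
  expect_error(init_weights(0), "positive")
})

test_that("weighted error sums the weights of misclassified samples", {
  y <- c(1, 1, -1, -1)
  expect_equal(weighted_error(y, y, rep(0.25, 4)), 0)
  expect_equal(weighted_error(c(-1, 1, -1, -1), y, rep(0.25, 4)), 0.25)
  # hand-summed oracle: wrong at samples 1 and 4
  expect_equal(weighted_error(c(-1, 1, -1, 1), y, c(0.5, 0.2, 0.2, 0.1)), 0.6)
  expect_error(weighted_error(c(1, 1), y, rep(0.25, 4)), "length")
})

test_that("voting weight is the half log-odds of the clamped error", {
  expect_equal(voting_weight(0.5), 0)
  expect_equal(voting_weight(0.1), 1.0986122886681096914, tolerance = 1e-13)
  expect_equal(voting_weight(0), 11.51292546492022842, tolerance = 1e-10)
  expect_true(is.finite(voting_weight(1)))
  expect_gt(voting_weight(0.2), 0)
  expect_lt(voting_weight(0.8), 0)
})

test_that("weight update shrinks correct samples, grows errors, renormalizes", {
  w <- c(0.5, 0.5)
  upd0 <- update_weights(w, 0, c(1, -1), c(1, 1))
  expect_identical(upd0$weights, w)  # exp(0) = 1, Z = 1
  expect_equal(upd0$Z, 1)
  # hand-evaluated: unnormalized [0.5 e^-0.5, 0.5 e^0.5]
  upd <- update_weights(w, 0.5, c(1, -1), c(1, 1))
  expect_equal(upd$weights, c(0.26894142136999512075, 0.73105857863000487925),
               tolerance = 1e-13)
  expect_equal(sum(upd$weights), 1, tolerance = 1e-12)
})

test_that("after an exact update the misclassified set carries mass 1/2", {
  set.seed(42)
  for (rep in 1:25) {
    n <- sample(5:20, 1)
    y <- sample(c(-1, 1), n, replace = TRUE)
    pred <- sample(c(-1, 1), n, replace = TRUE)
    if (all(pred == y) || all(pred != y)) next
    w <- runif(n); w <- w / sum(w)
    eps <- weighted_error(pred, y, w)
    d <- 0.5 * log((1 - eps) / eps)  # unclamped
    upd <- update_weights(w, d, y, pred)
    expect_equal(sum(upd$weights[pred != y]), 0.5, tolerance = 1e-12)
    expect_equal(sum(upd$weights), 1, tolerance = 1e-12)
  }
})

test_that("engine transcript matches a naive AdaBoost oracle with stumps", {
  set.seed(7)
  for (rep in 1:5) {
    n <- sample(8:20, 1)
    p <- sample(1:3, 1)
    X <- matrix(runif(n * p), n, p)
    y <- sample(c(-1, 1), n, replace = TRUE)
    if (length(unique(y)) < 2) next
    M <- sample(2:5, 1)
    oracle <- oracle_adaboost(X, y, M)
    ens <- suppressWarnings(
      fit_ensemble(X, y, M = M, learner = stump_learner(), seed = 1L))
    for (m in seq_len(M)) {
      expect_equal(ens$rounds[[m]]$epsilon, min(max(oracle$eps[m], 1e-10), 1 - 1e-10),
                   tolerance = 1e-10)
      expect_equal(ens$rounds[[m]]$d, oracle$d[m], tolerance = 1e-10)
    }
    expect_equal(ens$final_weights, oracle$weights[M + 1, ], tolerance = 1e-10)
  }
})

test_that("an M=1 ensemble reproduces its single learner exactly", {
  set.seed(12)
  X <- matrix(runif(30), 15, 2)
  y <- ifelse(X[, 1] > 0.5, 1, -1)
  ens <- fit_ensemble(X, y, M = 1, learner = stump_learner())
  single <- stump_learner()
  model <- single$fit(X, y, init_weights(15), 1L)
  for (voting in c("weighted", "simple")) {
    ens$voting <- voting
    expect_identical(predict_ensemble(ens, X)$label,
                     as.integer(single$predict(model, X)))
  }
})

test_that("boosting beats the best single stump on the classic 1D instance", {
  X <- matrix(c(1, 2, 3, 4, 5, 6, 7, 8), ncol = 1)
  y <- c(1, 1, 1, -1, -1, -1, 1, 1)
  best_single <- oracle_best_stump_error(X, y)
  ens <- fit_ensemble(X, y, M = 5, learner = stump_learner())
  boosted <- training_error(ens, X, y)$error
  expect_lt(boosted, best_single)
})

test_that("training error never exceeds the product bound, which is monotone", {
  set.seed(23)
  for (rep in 1:6) {
    n <- sample(10:20, 1)
    X <- matrix(runif(n * 2), n, 2)
    y <- sample(c(-1, 1), n, replace = TRUE)
    if (length(unique(y)) < 2) next
    ens <- suppressWarnings(
      fit_ensemble(X, y, M = 5, learner = stump_learner()))
    te <- training_error(ens, X, y)
    expect_lte(te$error, te$bound + 1e-12)
    expect_true(all(diff(ens$bound) <= 1e-12))
  }
})

test_that("permuting the samples permutes weights and leaves eps, d unchanged", {
  set.seed(31)
  n <- 14
  X <- matrix(runif(n * 2), n, 2)
  y <- sample(c(-1, 1), n, replace = TRUE)
  perm <- sample(n)
  a <- suppressWarnings(fit_ensemble(X, y, M = 3, learner = stump_learner()))
  b <- suppressWarnings(fit_ensemble(X[perm, , drop = FALSE], y[perm],
                                     M = 3, learner = stump_learner()))
  for (m in 1:3) {
    expect_equal(a$rounds[[m]]$epsilon, b$rounds[[m]]$epsilon, tolerance = 1e-12)
    expect_equal(a$rounds[[m]]$d, b$rounds[[m]]$d, tolerance = 1e-12)
  }
  expect_equal(a$final_weights[perm], b$final_weights, tolerance = 1e-12)
})

test_that("ensemble voting follows the sign-of-margin rule with +1 ties", {
  fixed <- function(preds) list(
    fit = function(x, y, w, seed) preds,
    predict = function(model, x) model)
  mk <- function(ds, preds_list) {
    rounds <- lapply(seq_along(ds), function(m)
      list(m = m, epsilon = 0.3, d = ds[m], Z = 1, model = preds_list[[m]]))
    structure(list(rounds = rounds, voting = "weighted",
                   learner = fixed(NULL), bound = 0.9),
              class = "ada_ensemble")
  }
  # d = [1, 2], predictions [+1, -1] -> margin -1, label -1
  ens <- mk(c(1, 2), list(1, -1))
  pe <- predict_ensemble(ens, "x")
  expect_equal(pe$margin, -1)
  expect_equal(pe$label, -1L)
  # d = [1, 1], predictions [+1, -1] -> margin 0 -> +1 by convention
  ens0 <- mk(c(1, 1), list(1, -1))
  pe0 <- predict_ensemble(ens0, "x")
  expect_equal(pe0$margin, 0)
  expect_equal(pe0$label, 1L)
  # simple voting ignores the vote magnitudes
  enss <- mk(c(0.2, 5.0, 0.1), list(1, -1, 1))
  enss$voting <- "simple"
  expect_equal(predict_ensemble(enss, "x")$label, 1L)
})

test_that("a round with error >= 0.5 warns and honors the epsilon policy", {
  # constant +1 learner: weighted error is exactly 0.5 on balanced data
  constant <- list(fit = function(x, y, w, seed) NULL,
                   predict = function(model, x) rep(1, 6))
  X <- matrix(1:6, ncol = 1)
  y <- c(1, -1, 1, -1, 1, -1)
  w <- capture_warnings(
    ens <- fit_ensemble(X, y, M = 3, learner = constant,
                        epsilon_policy = "continue"))
  expect_true(all(grepl(">= 0.5", w)))
  expect_length(w, 3L)  # every chance-level round warns
  expect_length(ens$rounds, 3L)
  suppressWarnings(
    ens2 <- fit_ensemble(X, y, M = 3, learner = constant,
                         epsilon_policy = "stop"))
  expect_length(ens2$rounds, 1L)
  expect_equal(ens2$rounds[[1]]$d, 0)  # eps = 0.5 gives a zero vote
})
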