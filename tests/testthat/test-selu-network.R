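test_that("selu matches its closed form and the frozen high-precision values", {
  expect_identical(selu(0), 0)
  expect_equal(selu(1), 1.0507, tolerance = 1e-15)
  expect_equal(selu(2), 2.1014, tolerance = 1e-15)
  # values frozen from a 40-digit evaluation of the closed form
  expect_equal(selu(-30), -1.7581363099998354802, tolerance = 1e-13)
  expect_equal(selu(-1), -1.1113541067739783193, tolerance = 1e-13)
  expect_equal(selu(-0.1), -0.16730879070433059756, tolerance = 1e-13)
  expect_equal(selu(-5), -1.7462900807260523035, tolerance = 1e-13)
  # saturation level is -lambda * alpha
  expect_equal(selu(-1e3), -1.0507 * 1.6733, tolerance = 1e-12)
  # continuity at 0 and shape preservation
  expect_lt(abs(selu(1e-12) - selu(-1e-12)), 1e-11)
  m <- matrix(c(-1, 0, 1, 2), 2)
  expect_equal(dim(selu(m)), dim(m))
})

test_that("selu gradient matches finite differences of selu", {
  xs <- c(-4, -1.5, -0.3, 0.2, 1.7, 5)
  h <- 1e-7
  num <- (selu(xs + h) - selu(xs - h)) / (2 * h)
  expect_equal(nodboost:::selu_grad(xs), num, tolerance = 1e-6)
})

test_that("alpha-dropout preserves mean and variance of standardized activations", {
  set.seed(21)
  x <- matrix(rnorm(2e5), ncol = 100)
  ad <- nodboost:::alpha_dropout(x, rate = 0.1)
  expect_equal(mean(ad$out), 0, tolerance = 0.02)
  expect_equal(var(as.vector(ad$out)), 1, tolerance = 0.05)
  expect_equal(mean(ad$keep), 0.9, tolerance = 0.01)
  # dropped units sit at the affine image of the saturation value
  a <- ad$a; ap <- -1.0507 * 1.6733; b <- -a * 0.1 * ap
  dropped <- ad$out[!ad$keep]
  expect_true(all(abs(dropped - (a * ap + b)) < 1e-12))
})

small_spec <- function(epochs = 5L) {
  base_learner_spec(input_size = 12L, n_views = 2L,
                    conv_blocks = list(c(4L, 3L), c(6L, 3L)),
                    fc_widths = 8L, batch_size = 8L,
                    learning_rate = 0.01, epochs = epochs, seed = 2L)
}

test_that("builds are seeded and deterministic; zero input scores 0.5", {
  l1 <- build_base_learner(small_spec())
  l2 <- build_base_learner(small_spec())
  expect_identical(l1$params, l2$params)
  zero_patch <- structure(list(views = array(0, c(12, 12, 2)), label = 1L,
                               candidate_id = "z"), class = "multiview_patch")
  expect_equal(predict_score(l1, zero_patch), 0.5, tolerance = 1e-12)
  set.seed(3)
  p <- structure(list(views = array(rnorm(12 * 12 * 2), c(12, 12, 2)),
                      label = 1L, candidate_id = "r"), class = "multiview_patch")
  s <- predict_score(l1, p)
  expect_true(s > 0 && s < 1)
  expect_identical(predict_score(build_base_learner(small_spec()), p), s)
})

test_that("network rejects shapes and depths it cannot process", {
  expect_error(build_base_learner(
    base_learner_spec(input_size = 4L, n_views = 1L,
                      conv_blocks = list(c(4L, 3L), c(4L, 3L)), fc_widths = 4L)),
    "conv block")
  lrn <- build_base_learner(small_spec())
  bad <- structure(list(views = array(0, c(10, 10, 2)), label = 1L,
                        candidate_id = "b"), class = "multiview_patch")
  expect_error(predict_score(lrn, bad), "expected 12x12x2, got 10x10x2")
})

test_that("analytic gradients match finite differences through the whole network", {
  spec <- base_learner_spec(input_size = 10L, n_views = 2L,
                            conv_blocks = list(c(3L, 3L)), fc_widths = 6L,
                            alpha_dropout_rate = 0, seed = 5L)
  lrn <- build_base_learner(spec)
  set.seed(8)
  N <- 4
  x4 <- array(rnorm(10 * 10 * 2 * N), dim = c(10, 10, 2, N))
  y01 <- c(1, 0, 0, 1)
  w <- c(1.5, 0.5, 1, 1)
  lg <- nodboost:::nn_loss_grad(lrn, x4, y01, w, training = FALSE)
  eps <- 1e-6
  for (nm in names(lrn$params)) {
    idxs <- sample(length(lrn$params[[nm]]), min(5, length(lrn$params[[nm]])))
    for (i in idxs) {
      l2 <- lrn
      l2$params[[nm]][i] <- l2$params[[nm]][i] + eps
      lp <- nodboost:::nn_loss_grad(l2, x4, y01, w, training = FALSE)$loss
      l2$params[[nm]][i] <- l2$params[[nm]][i] - 2 * eps
      lm <- nodboost:::nn_loss_grad(l2, x4, y01, w, training = FALSE)$loss
      num <- (lp - lm) / (2 * eps)
      expect_equal(lg$grads[[nm]][i], num, tolerance = 1e-4,
                   label = sprintf("grad %s[%d]", nm, i))
    }
  }
})

test_that("max-pooling selects the maximum of each 2x2 receptive field", {
  spec <- base_learner_spec(input_size = 8L, n_views = 1L,
                            conv_blocks = list(c(2L, 3L)), fc_widths = 4L,
                            alpha_dropout_rate = 0, seed = 1L)
  lrn <- build_base_learner(spec)
  set.seed(10)
  x4 <- array(rnorm(8 * 8 * 1 * 2), dim = c(8, 8, 1, 2))
  fw <- nodboost:::nn_forward(lrn, x4, keep_cache = TRUE)
  cc <- fw$cache$conv[[1]]
  plan <- cc$plan
  A <- nodboost:::selu(cc$Z)
  A4 <- aperm(array(A, dim = c(plan$Ho, plan$Wo, 2, cc$f)), c(1, 2, 4, 3))
  for (s in 1:2) for (f in 1:cc$f) for (i in seq_len(cc$Hp)) for (j in seq_len(cc$Wp)) {
    win <- A4[(2 * i - 1):(2 * i), (2 * j - 1):(2 * j), f, s]
    pooled <- max(win)
    expect_true(pooled %in% win)
    expect_true(all(pooled >= win))
  }
})

test_that("training learns a separable toy set as well as a logistic oracle", {
  patches <- make_toy_patches(60, size = 12L, n_views = 2L, amp = 2, seed = 13)
  y <- vapply(patches, `[[`, numeric(1), "label")
  lrn <- train_base_learner(build_base_learner(small_spec()), patches)
  acc <- mean(score_to_label(predict_score(lrn, patches)) == y)
  expect_gte(acc, 0.95)
  # independent oracle: regularized logistic regression on flattened pixels
  X <- t(vapply(patches, function(p) as.vector(p$views), numeric(12 * 12 * 2)))
  fit <- suppressWarnings(glm.fit(cbind(1, X), (y + 1) / 2,
                                  family = binomial()))
  oracle_acc <- mean((fit$fitted.values >= 0.5) == (y > 0))
  expect_gte(oracle_acc, 0.95)
})

test_that("training is weight-scale invariant and deterministic given a seed", {
  patches <- make_toy_patches(20, size = 12L, n_views = 2L, seed = 31)
  set.seed(17)
  w <- runif(20)
  a <- train_base_learner(build_base_learner(small_spec(epochs = 2L)), patches,
                          sample_weights = w)
  b <- train_base_learner(build_base_learner(small_spec(epochs = 2L)), patches,
                          sample_weights = 2 * w)
  expect_identical(a$params, b$params)
  expect_identical(a$history, b$history)
})

test_that("a zero-weight mislabeled duplicate does not alter the loss trajectory", {
  spec <- base_learner_spec(input_size = 12L, n_views = 2L,
                            conv_blocks = list(c(4L, 3L)), fc_widths = 8L,
                            alpha_dropout_rate = 0,  # full-batch, noise-free
                            batch_size = 64L, learning_rate = 0.01,
                            epochs = 4L, seed = 6L)
  patches <- make_toy_patches(20, size = 12L, n_views = 2L, seed = 41)
  w <- rep(1 / 20, 20)
  dup <- patches[[1]]
  dup$label <- -dup$label
  a <- train_base_learner(build_base_learner(spec), patches, sample_weights = w)
  b <- train_base_learner(build_base_learner(spec), c(patches, list(dup)),
                          sample_weights = c(w, 0))
  expect_equal(a$history, b$history, tolerance = 1e-8)
})

test_that("degenerate training inputs raise clear errors", {
  patches <- make_toy_patches(10, size = 12L, n_views = 2L, seed = 3)
  lrn <- build_base_learner(small_spec())
  expect_error(train_base_learner(lrn, list()), "empty")
  onecls <- patches[1:5]  # all +1 by construction
  expect_error(train_base_learner(lrn, onecls), "same label")
  expect_error(train_base_learner(lrn, patches, sample_weights = rep(-1, 10)),
               "nonnegative")
})

test_that("batch prediction equals sample-by-sample prediction", {
  patches <- make_toy_patches(12, size = 12L, n_views = 2L, seed = 55)
  lrn <- train_base_learner(build_base_learner(small_spec(epochs = 1L)), patches)
  batch <- predict_score(lrn, patches)
  single <- vapply(patches, function(p) predict_score(lrn, p), numeric(1))
  expect_equal(batch, single, tolerance = 1e-12)
  expect_identical(score_to_label(c(0.7, 0.5, 0.49)), c(1L, 1L, -1L))
})
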