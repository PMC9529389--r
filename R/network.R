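#' Base-learner architecture and training hyperparameters
#'
#' Describes the self-normalizing multiview CNN used as the boosting base
#' learner: a stack of `[convolution -> SELU -> 2x2 max-pool]` blocks over
#' the multiview channel stack, fully connected SELU layers with
#' alpha-dropout, and a single sigmoid output unit giving P(nodule).
#'
#' Constructor defaults mirror full-scale training (input 224, Adam with
#' learning rate 1e-4 and first-moment decay 0.9, binary cross-entropy,
#' batch size 128). The desk-scale profile used in examples, tests and
#' [run_config()] overrides `input_size = 32`, `batch_size = 4`,
#' `learning_rate = 0.005` and a few epochs so that training runs in seconds
#' on one CPU.
#'
#' @param input_size pixel side length of each view plane.
#' @param n_views number of views (input channels).
#' @param conv_blocks list of `c(n_filters, kernel_size)` pairs.
#' @param fc_widths integer vector of fully connected hidden widths.
#' @param alpha_dropout_rate alpha-dropout probability on fully connected
#'   hidden activations.
#' @param selu_alpha,selu_lambda SELU constants.
#' @param learning_rate Adam step size.
#' @param beta1 Adam first-moment decay (the "momentum" hyperparameter).
#' @param beta2 Adam second-moment decay.
#' @param batch_size minibatch size.
#' @param epochs training epochs.
#' @param seed integer; fixes weight initialization, shuffling and dropout.
#' @return An object of class `base_learner_spec`.
#' @export
base_learner_spec <- function(input_size = 224L,
                              n_views = 3L,
                              conv_blocks = list(c(8L, 3L), c(16L, 3L)),
                              fc_widths = 32L,
                              alpha_dropout_rate = 0.05,
                              selu_alpha = 1.6733,
                              selu_lambda = 1.0507,
                              learning_rate = 1e-4,
                              beta1 = 0.9,
                              beta2 = 0.999,
                              batch_size = 128L,
                              epochs = 3L,
                              seed = 1L) {
  if (length(conv_blocks) == 0L || length(fc_widths) == 0L)
    stopf("conv_blocks and fc_widths must be non-empty")
  if (alpha_dropout_rate < 0 || alpha_dropout_rate >= 1)
    stopf("alpha_dropout_rate must be in [0, 1)")
  if (selu_alpha <= 1 || selu_lambda <= 1)
    stopf("SELU constants must satisfy alpha > 1, lambda > 1")
  structure(list(
    input_size = as.integer(input_size),
    n_views = as.integer(n_views),
    conv_blocks = lapply(conv_blocks, as.integer),
    fc_widths = as.integer(fc_widths),
    alpha_dropout_rate = alpha_dropout_rate,
    selu_alpha = selu_alpha,
    selu_lambda = selu_lambda,
    learning_rate = learning_rate,
    beta1 = beta1,
    beta2 = beta2,
    batch_size = as.integer(batch_size),
    epochs = as.integer(epochs),
    seed = as.integer(seed)
  ), class = "base_learner_spec")
}

# im2col index plan for one convolution layer: linear indices into an
# [H, W, C] array for every (output position) x (kernel offset, channel).
conv_plan <- function(H, W, C, k) {
  Ho <- H - k + 1L
  Wo <- W - k + 1L
  npos <- Ho * Wo
  i <- rep(seq_len(Ho), times = Wo)
  j <- rep(seq_len(Wo), each = Ho)
  lin0 <- i + (j - 1L) * H
  di <- rep(seq_len(k), times = k * C)
  dj <- rep(rep(seq_len(k), each = k), times = C)
  cc <- rep(seq_len(C), each = k * k)
  off <- (di - 1L) + (dj - 1L) * H + (cc - 1L) * H * W
  list(H = H, W = W, C = C, k = k, Ho = Ho, Wo = Wo, npos = npos,
       idx = outer(lin0, off, `+`))
}

# replicate the per-sample index plan across a batch of N samples stacked in
# the 4th dimension of an [H, W, C, N] array
batch_idx <- function(plan, N) {
  plan$idx[rep(seq_len(plan$npos), times = N), , drop = FALSE] +
    rep(seq_len(N) - 1L, each = plan$npos) * (plan$H * plan$W * plan$C)
}

#' Build an untrained self-normalizing multiview CNN
#'
#' Lays out the network described by a [base_learner_spec()] and initializes
#' weights with the self-normalizing scheme (zero-mean normal, variance
#' `1/fan_in`; biases zero) under the spec's seed, so two learners built
#' from the same spec are identical.
#'
#' @param spec a [base_learner_spec()].
#' @return An object of class `snmv_learner` with elements `spec`, `plans`
#'   (per-layer shape bookkeeping) and `params` (named list of weight
#'   arrays).
#' @export
build_base_learner <- function(spec) {
  if (!inherits(spec, "base_learner_spec")) stopf("spec must be a base_learner_spec")
  plans <- list()
  s <- spec$input_size
  C <- spec$n_views
  for (l in seq_along(spec$conv_blocks)) {
    k <- spec$conv_blocks[[l]][2]
    f <- spec$conv_blocks[[l]][1]
    if (s - k + 1L < 2L)
      stopf("input size too small for conv block %d: %d pixels left before a %dx%d kernel",
            l, s, k, k)
    plans[[l]] <- conv_plan(s, s, C, k)
    s <- (s - k + 1L) %/% 2L  # valid conv then 2x2 max-pool (floor)
    if (s < 1L)
      stopf("input size too small for the pooling depth at conv block %d", l)
    C <- f
  }
  flat_dim <- s * s * C
  params <- with_seed(spec$seed, {
    p <- list()
    Cin <- spec$n_views
    for (l in seq_along(spec$conv_blocks)) {
      k <- spec$conv_blocks[[l]][2]
      f <- spec$conv_blocks[[l]][1]
      fan_in <- k * k * Cin
      p[[sprintf("conv%d.W", l)]] <-
        matrix(rnorm(fan_in * f, sd = 1 / sqrt(fan_in)), fan_in, f)
      p[[sprintf("conv%d.b", l)]] <- numeric(f)
      Cin <- f
    }
    d <- flat_dim
    for (l in seq_along(spec$fc_widths)) {
      w <- spec$fc_widths[l]
      p[[sprintf("fc%d.W", l)]] <- matrix(rnorm(d * w, sd = 1 / sqrt(d)), d, w)
      p[[sprintf("fc%d.b", l)]] <- numeric(w)
      d <- w
    }
    p[["out.W"]] <- matrix(rnorm(d, sd = 1 / sqrt(d)), d, 1)
    p[["out.b"]] <- 0
    p
  })
  structure(list(spec = spec, plans = plans, flat_dim = flat_dim,
                 params = params, trained = FALSE),
            class = "snmv_learner")
}

# forward pass over an [H, W, C, N] batch; returns logits and, when
# `keep_cache`, everything backward needs
nn_forward <- function(learner, x4, training = FALSE, keep_cache = FALSE) {
  spec <- learner$spec
  p <- learner$params
  al <- spec$selu_alpha
  la <- spec$selu_lambda
  N <- dim(x4)[4]
  cache <- list(conv = list(), fc = list())
  a <- x4
  for (l in seq_along(spec$conv_blocks)) {
    plan <- learner$plans[[l]]
    idx <- batch_idx(plan, N)
    Xc <- matrix(a[idx], nrow = plan$npos * N)
    Z <- Xc %*% p[[sprintf("conv%d.W", l)]]
    Z <- Z + rep(p[[sprintf("conv%d.b", l)]], each = nrow(Z))
    A <- selu(Z, al, la)
    f <- spec$conv_blocks[[l]][1]
    A4 <- aperm(array(A, dim = c(plan$Ho, plan$Wo, N, f)), c(1, 2, 4, 3))
    # 2x2 max-pool, stride 2, floor (odd trailing row/col dropped)
    Hp <- plan$Ho %/% 2L
    Wp <- plan$Wo %/% 2L
    odd_i <- seq.int(1L, 2L * Hp, by = 2L)
    odd_j <- seq.int(1L, 2L * Wp, by = 2L)
    s00 <- A4[odd_i, odd_j, , , drop = FALSE]
    s10 <- A4[odd_i + 1L, odd_j, , , drop = FALSE]
    s01 <- A4[odd_i, odd_j + 1L, , , drop = FALSE]
    s11 <- A4[odd_i + 1L, odd_j + 1L, , , drop = FALSE]
    m <- pmax(s00, s10, s01, s11)
    if (keep_cache) {
      m00 <- s00 == m
      m10 <- (s10 == m) & !m00
      m01 <- (s01 == m) & !m00 & !m10
      m11 <- (s11 == m) & !m00 & !m10 & !m01
      cache$conv[[l]] <- list(Xc = Xc, Z = Z, idx = idx, plan = plan,
                              Hp = Hp, Wp = Wp, f = f,
                              masks = list(m00, m10, m01, m11),
                              in_dim = dim(a))
    }
    a <- m
  }
  D <- learner$flat_dim
  Amat <- t(matrix(a, nrow = D, ncol = N))
  if (keep_cache) cache$flat_in_dim <- dim(a)
  for (l in seq_along(spec$fc_widths)) {
    Z <- Amat %*% p[[sprintf("fc%d.W", l)]]
    Z <- Z + rep(p[[sprintf("fc%d.b", l)]], each = nrow(Z))
    A <- selu(Z, al, la)
    dpo <- if (training && spec$alpha_dropout_rate > 0)
      alpha_dropout(A, spec$alpha_dropout_rate, al, la)
    else list(out = A, keep = NULL, a = 1)
    if (keep_cache)
      cache$fc[[l]] <- list(Ain = Amat, Z = Z, keep = dpo$keep, dscale = dpo$a)
    Amat <- dpo$out
  }
  logits <- drop(Amat %*% p[["out.W"]] + p[["out.b"]])
  if (keep_cache) cache$out_in <- Amat
  list(logits = logits, cache = if (keep_cache) cache else NULL)
}

nn_backward <- function(learner, cache, dlogits) {
  spec <- learner$spec
  p <- learner$params
  al <- spec$selu_alpha
  la <- spec$selu_lambda
  g <- list()
  N <- length(dlogits)
  dl <- matrix(dlogits, ncol = 1)
  g[["out.W"]] <- t(cache$out_in) %*% dl
  g[["out.b"]] <- sum(dl)
  dA <- dl %*% t(p[["out.W"]])
  for (l in rev(seq_along(spec$fc_widths))) {
    cc <- cache$fc[[l]]
    if (!is.null(cc$keep)) dA <- dA * cc$dscale * cc$keep
    dZ <- dA * selu_grad(cc$Z, al, la)
    g[[sprintf("fc%d.W", l)]] <- t(cc$Ain) %*% dZ
    g[[sprintf("fc%d.b", l)]] <- colSums(dZ)
    dA <- dZ %*% t(p[[sprintf("fc%d.W", l)]])
  }
  dA4 <- array(t(dA), dim = cache$flat_in_dim)
  for (l in rev(seq_along(spec$conv_blocks))) {
    cc <- cache$conv[[l]]
    plan <- cc$plan
    # un-pool: route gradient to the argmax cell of each 2x2 window
    dPre <- array(0, dim = c(plan$Ho, plan$Wo, cc$f, N))
    odd_i <- seq.int(1L, 2L * cc$Hp, by = 2L)
    odd_j <- seq.int(1L, 2L * cc$Wp, by = 2L)
    dPre[odd_i, odd_j, , ] <- dA4 * cc$masks[[1]]
    dPre[odd_i + 1L, odd_j, , ] <- dA4 * cc$masks[[2]]
    dPre[odd_i, odd_j + 1L, , ] <- dA4 * cc$masks[[3]]
    dPre[odd_i + 1L, odd_j + 1L, , ] <- dA4 * cc$masks[[4]]
    dAmat <- matrix(aperm(dPre, c(1, 2, 4, 3)), nrow = plan$npos * N)
    dZ <- dAmat * selu_grad(cc$Z, al, la)
    g[[sprintf("conv%d.W", l)]] <- t(cc$Xc) %*% dZ
    g[[sprintf("conv%d.b", l)]] <- colSums(dZ)
    if (l > 1L) {
      dXc <- dZ %*% t(p[[sprintf("conv%d.W", l)]])
      dx <- numeric(prod(cc$in_dim))
      rs <- rowsum(as.vector(dXc), group = as.vector(cc$idx))
      dx[as.integer(rownames(rs))] <- rs[, 1]
      dA4 <- array(dx, dim = cc$in_dim)
    }
  }
  g
}

# weighted binary cross-entropy (stable logit form) and its gradient;
# y01 in {0,1}, w per-sample weights (mean ~ 1)
nn_loss_grad <- function(learner, x4, y01, w, training = TRUE) {
  fw <- nn_forward(learner, x4, training = training, keep_cache = TRUE)
  z <- fw$logits
  n <- length(z)
  loss_i <- pmax(z, 0) - z * y01 + log1p(exp(-abs(z)))
  loss <- mean(w * loss_i)
  probs <- 1 / (1 + exp(-z))
  dlogits <- w * (probs - y01) / n
  grads <- nn_backward(learner, fw$cache, dlogits)
  list(loss = loss, grads = grads, probs = probs)
}

adam_step <- function(params, grads, state, lr, b1, b2, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - b1^state$t
  bc2 <- 1 - b2^state$t
  for (nm in names(grads)) {
    gnm <- grads[[nm]]
    state$m[[nm]] <- b1 * state$m[[nm]] + (1 - b1) * gnm
    state$v[[nm]] <- b2 * state$v[[nm]] + (1 - b2) * gnm^2
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}

# stack a list of multiview patches into an [H, W, C, N] batch array
patches_to_batch <- function(patches, spec) {
  H <- spec$input_size
  C <- spec$n_views
  N <- length(patches)
  x4 <- array(0, dim = c(H, H, C, N))
  for (i in seq_len(N)) {
    v <- patches[[i]]$views
    if (!identical(dim(v), c(H, H, C)))
      stopf("patch %d shape mismatch: expected %dx%dx%d, got %s",
            i, H, H, C, paste(dim(v), collapse = "x"))
    x4[, , , i] <- v
  }
  x4
}

patch_labels <- function(patches) vapply(patches, function(p) p$label, numeric(1))

#' Train a base learner with per-sample weights
#'
#' Minimizes sample-weighted binary cross-entropy with Adam under the spec's
#' hyperparameters. The incoming boosting weights are first normalized to
#' sum 1, then rescaled to mean 1 (`w_i = n * S_i`) so that uniform weights
#' reproduce the unweighted loss and rescaling all weights by a constant
#' changes nothing. Training is deterministic given the seed and data order:
#' shuffling and dropout masks are drawn from a generator seeded from
#' `spec$seed` (or `seed` if given).
#'
#' @param learner an untrained [build_base_learner()] result.
#' @param patches list of `multiview_patch` objects (labels +1/-1).
#' @param sample_weights nonnegative weights, one per patch; `NULL` for
#'   uniform.
#' @param seed optional override of the training seed.
#' @return The trained learner, with a `history` element recording the loss
#'   after every minibatch update.
#' @export
train_base_learner <- function(learner, patches, sample_weights = NULL, seed = NULL) {
  if (!inherits(learner, "snmv_learner")) stopf("learner must be an snmv_learner")
  spec <- learner$spec
  n <- length(patches)
  if (n == 0L) stopf("cannot train on empty data")
  y <- patch_labels(patches)
  if (length(unique(y)) < 2L)
    stopf("cannot train: all %d samples have the same label (%+d)", n, y[1])
  if (is.null(sample_weights)) sample_weights <- rep(1 / n, n)
  if (length(sample_weights) != n)
    stopf("sample_weights length %d does not match %d samples", length(sample_weights), n)
  if (any(sample_weights < 0)) stopf("sample_weights must be nonnegative")
  S <- sample_weights / sum(sample_weights)
  w <- n * S  # mean-1 per-sample loss weights
  y01 <- as.numeric(y > 0)
  x4 <- patches_to_batch(patches, spec)

  train_seed <- if (is.null(seed)) spec$seed else as.integer(seed)
  state <- list(t = 0L,
                m = lapply(learner$params, function(x) x * 0),
                v = lapply(learner$params, function(x) x * 0))
  history <- numeric(0)
  learner <- with_seed(derive_seed(train_seed, 17L), {
    for (ep in seq_len(spec$epochs)) {
      perm <- sample.int(n)
      starts <- seq.int(1L, n, by = spec$batch_size)
      for (s in starts) {
        ids <- perm[s:min(s + spec$batch_size - 1L, n)]
        lg <- nn_loss_grad(learner, x4[, , , ids, drop = FALSE],
                           y01[ids], w[ids], training = TRUE)
        upd <- adam_step(learner$params, lg$grads, state,
                         spec$learning_rate, spec$beta1, spec$beta2)
        learner$params <- upd$params
        state <- upd$state
        history <- c(history, lg$loss)
      }
    }
    learner
  })
  learner$trained <- TRUE
  learner$history <- history
  learner
}

#' Predict nodule probabilities
#'
#' Returns `P(nodule)` in (0, 1) for one patch or a list of patches. The
#' hard label convention is `+1` iff the score is `>= 0.5` (see
#' [score_to_label()]); batch prediction is elementwise identical to
#' sample-by-sample prediction.
#'
#' @param learner a trained (or untrained) `snmv_learner`.
#' @param patches one `multiview_patch` or a list of them.
#' @return Numeric vector of probabilities.
#' @export
predict_score <- function(learner, patches) {
  if (inherits(patches, "multiview_patch")) patches <- list(patches)
  x4 <- patches_to_batch(patches, learner$spec)
  scores <- numeric(length(patches))
  chunk <- 256L
  for (s in seq.int(1L, length(patches), by = chunk)) {
    ids <- s:min(s + chunk - 1L, length(patches))
    z <- nn_forward(learner, x4[, , , ids, drop = FALSE], training = FALSE)$logits
    scores[ids] <- 1 / (1 + exp(-z))
  }
  scores
}

#' Convert probability scores to hard labels
#'
#' @param scores probabilities in (0, 1).
#' @return `+1` where `scores >= 0.5`, else `-1` (ties go to the positive
#'   class).
#' @export
score_to_label <- function(scores) ifelse(scores >= 0.5, 1L, -1L)
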