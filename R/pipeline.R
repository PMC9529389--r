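#' Assemble a full run configuration
#'
#' Bundles the phantom, extraction, learner and boosting settings behind one
#' master seed, from which every stochastic stage (phantom placement, split,
#' per-round learner seeds) derives its own seed.
#'
#' Two profiles are provided. `"desk"` (default) is sized to complete in
#' minutes on one CPU: 32x32 network input, 100 candidates, minibatch 4,
#' Adam learning rate 0.005, 3 boosting rounds of 3 epochs.
#' `"full"` keeps the full-scale training hyperparameters (224x224 input,
#' batch 128, learning rate 1e-4); it is configuration surface, not
#' something the test suite trains.
#'
#' @param master_seed integer master seed.
#' @param profile `"desk"` or `"full"`.
#' @param phantom,views,learner optional [phantom_config()], [view_config()],
#'   [base_learner_spec()] overriding the profile.
#' @param rounds boosting rounds M.
#' @param voting `"weighted"` or `"simple"`.
#' @param epsilon_policy `"continue"` or `"stop"`.
#' @param test_frac held-out test fraction.
#' @return An object of class `run_config`.
#' @export
run_config <- function(master_seed = 1L,
                       profile = c("desk", "full"),
                       phantom = NULL, views = NULL, learner = NULL,
                       rounds = 3L,
                       voting = c("weighted", "simple"),
                       epsilon_policy = c("continue", "stop"),
                       test_frac = 0.2) {
  profile <- match.arg(profile)
  voting <- match.arg(voting)
  epsilon_policy <- match.arg(epsilon_policy)
  if (is.null(phantom))
    phantom <- phantom_config(seed = derive_seed(master_seed, 1L))
  if (is.null(views))
    views <- if (profile == "desk") view_config(target_size = 32L)
             else view_config(target_size = 224L)
  if (is.null(learner)) {
    learner <- if (profile == "desk")
      base_learner_spec(input_size = views$target_size,
                        n_views = length(views$crop_sizes),
                        batch_size = 4L, learning_rate = 0.005, epochs = 3L)
    else
      base_learner_spec(input_size = views$target_size,
                        n_views = length(views$crop_sizes))
  }
  structure(list(
    master_seed = as.integer(master_seed),
    profile = profile,
    phantom = phantom,
    views = views,
    learner = learner,
    boosting = list(M = as.integer(rounds), voting = voting,
                    epsilon_policy = epsilon_policy),
    evaluation = list(test_frac = test_frac)
  ), class = "run_config")
}

#' Save and load run configurations
#'
#' Round-trips a [run_config()] through JSON losslessly.
#'
#' @param config a `run_config`.
#' @param path JSON file path.
#' @name run_config_io
#' @export
save_run_config <- function(config, path) {
  write_json_report(unclass_deep(config), path)
}

unclass_deep <- function(x) {
  if (is.list(x)) lapply(unclass(x), unclass_deep) else x
}

#' @rdname run_config_io
#' @export
load_run_config <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  cb <- j$learner$conv_blocks
  if (is.matrix(cb)) cb <- lapply(seq_len(nrow(cb)), function(i) cb[i, ])
  j$learner$conv_blocks <- cb
  run_config(
    master_seed = j$master_seed,
    profile = j$profile,
    phantom = do.call(phantom_config, j$phantom),
    views = do.call(view_config, j$views),
    learner = base_learner_spec(
      input_size = j$learner$input_size, n_views = j$learner$n_views,
      conv_blocks = j$learner$conv_blocks, fc_widths = j$learner$fc_widths,
      alpha_dropout_rate = j$learner$alpha_dropout_rate,
      selu_alpha = j$learner$selu_alpha, selu_lambda = j$learner$selu_lambda,
      learning_rate = j$learner$learning_rate, beta1 = j$learner$beta1,
      beta2 = j$learner$beta2, batch_size = j$learner$batch_size,
      epochs = j$learner$epochs, seed = j$learner$seed),
    rounds = j$boosting$M, voting = j$boosting$voting,
    epsilon_policy = j$boosting$epsilon_policy,
    test_frac = j$evaluation$test_frac
  )
}

log_line <- function(con, stage, msg) {
  cat(sprintf("[%s] stage=%s %s\n", format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
              stage, msg), file = con, append = TRUE)
}

#' Run the full phantom-to-metrics pipeline
#'
#' Executes simulate -> extract -> stratified 80/20 split -> boosted
#' training on the training split -> weighted-vote prediction on the test
#' split -> metrics and ROC report. The run directory holds the
#' configuration copy, volume, candidate table, patch manifest, serialized
#' ensemble and reports; the whole run is reproducible from the directory
#' alone, and identical configuration plus master seed gives a byte-identical
#' metrics report.
#'
#' @param config a [run_config()].
#' @param out_dir output run directory (created if needed).
#' @param write_volume_file write the phantom volume as NIfTI (default TRUE).
#' @param write_archive also write the per-candidate patch archive (slower;
#'   default FALSE).
#' @return Invisibly, a list with `metrics`, `roc`, `ensemble`, `split` and
#'   `dir`.
#' @export
run_pipeline <- function(config, out_dir,
                         write_volume_file = TRUE, write_archive = FALSE) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  logf <- file.path(out_dir, "run.log")
  cat("", file = logf)
  save_run_config(config, file.path(out_dir, "config.json"))

  log_line(logf, "simulate", sprintf("seed=%d", config$phantom$seed))
  ph <- tryCatch(generate_phantom(config$phantom),
                 error = function(e) stopf("stage simulate failed: %s", conditionMessage(e)))
  if (write_volume_file) write_volume(ph$volume, file.path(out_dir, "volume.nii.gz"))
  write_candidates(ph$candidates, file.path(out_dir, "candidates.csv"))

  log_line(logf, "extract", sprintf("n=%d views=%d target=%d",
                                    nrow(ph$candidates),
                                    length(config$views$crop_sizes),
                                    config$views$target_size))
  patches <- extract_all(ph$volume, ph$candidates, config$views)
  manifest <- data.frame(candidate_id = ph$candidates$candidate_id,
                         label = ifelse(ph$candidates$label > 0, 1L, 0L),
                         n_views = length(config$views$crop_sizes),
                         target_size = config$views$target_size)
  write.csv(manifest, file.path(out_dir, "manifest.csv"),
            row.names = FALSE, quote = FALSE)
  if (write_archive)
    extract_archive(ph$volume, ph$candidates, config$views,
                    file.path(out_dir, "patches"))

  split_seed <- derive_seed(config$master_seed, 2L)
  sp <- split_80_20(ph$candidates, seed = split_seed,
                    test_frac = config$evaluation$test_frac)
  ids <- ph$candidates$candidate_id
  train_idx <- match(sp$train, ids)
  test_idx <- match(sp$test, ids)
  log_line(logf, "split", sprintf("train=%d test=%d seed=%d",
                                  length(train_idx), length(test_idx), split_seed))

  boost_seed <- derive_seed(config$master_seed, 3L)
  log_line(logf, "train", sprintf("M=%d voting=%s seed=%d",
                                  config$boosting$M, config$boosting$voting, boost_seed))
  ens <- tryCatch(
    fit_ensemble(patches[train_idx], ph$candidates$label[train_idx],
                 M = config$boosting$M, learner = cnn_learner(config$learner),
                 seed = boost_seed, voting = config$boosting$voting,
                 epsilon_policy = config$boosting$epsilon_policy),
    error = function(e) stopf("stage train failed: %s", conditionMessage(e)))

  log_line(logf, "predict", sprintf("n=%d", length(test_idx)))
  pe <- predict_ensemble(ens, patches[test_idx])
  true <- ph$candidates$label[test_idx]
  m <- metrics(confusion(pe$label, true))
  rc <- roc(pe$margin, true)

  report <- list(
    n_train = length(train_idx), n_test = length(test_idx),
    accuracy = m$accuracy, sensitivity = m$sensitivity,
    specificity = m$specificity, auc = rc$auc,
    rounds = lapply(ens$rounds, function(r)
      list(m = r$m, epsilon = r$epsilon, d = r$d, Z = r$Z, seed = r$seed)),
    voting = ens$voting, master_seed = config$master_seed
  )
  write_json_report(report, file.path(out_dir, "metrics.json"))
  write.csv(rc$points, file.path(out_dir, "roc.csv"), row.names = FALSE, quote = FALSE)
  ensemble_meta <- list(
    voting = ens$voting,
    rounds = lapply(ens$rounds, function(r)
      list(m = r$m, epsilon = r$epsilon, d = r$d, Z = r$Z, seed = r$seed))
  )
  write_json_report(ensemble_meta, file.path(out_dir, "ensemble.json"))
  saveRDS(ens, file.path(out_dir, "ensemble.rds"))
  log_line(logf, "done", sprintf("accuracy=%.4f auc=%.4f", m$accuracy, rc$auc))

  invisible(list(metrics = report, roc = rc, ensemble = ens,
                 split = sp, dir = out_dir))
}
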