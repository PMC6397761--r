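#' Run configuration
#'
#' Assembles the configuration shared by the [run_train()], [run_predict()],
#' [run_evaluate()], [run_cv()] and [run_simulate()] workflow drivers. Every
#' field has a documented default and the configuration round-trips through
#' JSON ([write_run_config()] / [read_run_config()]).
#'
#' @param train_table,test_table paths to instance-table CSVs
#'   (see [read_instance_table()]).
#' @param model_dir directory for the persisted model.
#' @param out output path (predictions CSV, report directory, ...).
#' @param level `"genus"`, `"species"`, or `"hierarchical"`.
#' @param pairs_mode `"one"` or `"two"` classifiers per pair.
#' @param seed integer seed (splits and vote-tie breaking).
#' @param lambda background covariance ridge weight.
#' @param max_iter maximum MI-ACE iterations.
#' @param water_band_ranges list of nm intervals removed before training;
#'   default [water_band_ranges()].
#' @param drop_labels labels removed from the training set at both levels
#'   (default `"OTHERS"`).
#' @param epsilon optional softening epsilon for reported probabilities.
#' @param cv_repeats repeated-split count for [run_cv()].
#' @param verbose print progress messages.
#' @return A list of class `run_config`.
#' @export
run_config <- function(train_table = NULL, test_table = NULL,
                       model_dir = NULL, out = NULL,
                       level = "hierarchical", pairs_mode = "one",
                       seed = 1L, lambda = 1e-6, max_iter = 1000,
                       water_band_ranges = NULL,
                       drop_labels = "OTHERS", epsilon = NULL,
                       cv_repeats = 10, verbose = TRUE) {
  if (is.null(water_band_ranges))
    water_band_ranges <- miace::water_band_ranges()
  structure(list(train_table = train_table, test_table = test_table,
                 model_dir = model_dir, out = out, level = level,
                 pairs_mode = pairs_mode, seed = as.integer(seed),
                 lambda = lambda, max_iter = max_iter,
                 water_band_ranges = water_band_ranges,
                 drop_labels = drop_labels, epsilon = epsilon,
                 cv_repeats = cv_repeats, verbose = verbose),
            class = "run_config")
}

#' @rdname run_config
#' @param config a `run_config`.
#' @param path JSON file path.
#' @export
write_run_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname run_config
#' @export
read_run_config <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  wbr <- j$water_band_ranges
  if (is.matrix(wbr)) wbr <- lapply(seq_len(nrow(wbr)), function(i) wbr[i, ])
  else if (is.numeric(wbr)) wbr <- list(as.numeric(wbr))
  else wbr <- lapply(wbr, as.numeric)
  j$water_band_ranges <- wbr
  do.call(run_config, j)
}

say <- function(config, ...) if (isTRUE(config$verbose)) message(sprintf(...))

load_training_set <- function(config) {
  if (is.null(config$train_table)) stop("config$train_table is required")
  x <- read_instance_table(config$train_table)
  x <- remove_water_bands(x, config$water_band_ranges)
  for (lab in config$drop_labels) {
    x <- drop_label(x, lab, "genus")
    if (!is.null(x)) x <- drop_label(x, lab, "species")
  }
  if (is.null(x)) stop("no training crowns left after label filtering")
  x
}

#' Train a one-vs-one MI-ACE model from a config
#'
#' Reads the training table, removes water bands and dropped labels, trains
#' the one-vs-one model at the configured level (`"hierarchical"` trains the
#' genus model plus per-genus species sub-models), persists it to
#' `config$model_dir` and writes a per-classifier training report
#' (`training_report.csv`: target, background, objective, threshold,
#' training accuracy).
#'
#' @param config a [run_config()] with `train_table` and `model_dir` set.
#' @return The trained `miace_ovo` model, invisibly.
#' @export
run_train <- function(config) {
  x <- load_training_set(config)
  say(config, "training on %d crowns, %d bands", n_bags(x), n_bands(x))
  model <- if (config$level == "hierarchical") {
    miace_ovo(x, level = "genus", pairs_mode = config$pairs_mode,
              hierarchical = TRUE, lambda = config$lambda,
              max_iter = config$max_iter)
  } else {
    miace_ovo(x, level = config$level, pairs_mode = config$pairs_mode,
              lambda = config$lambda, max_iter = config$max_iter)
  }
  if (is.null(config$model_dir)) stop("config$model_dir is required")
  write_miace_model(model, config$model_dir)
  report <- data.frame(
    target = vapply(model$classifiers, `[[`, "", "target_class"),
    background = vapply(model$classifiers, `[[`, "", "background_class"),
    objective = vapply(model$classifiers, function(c) c$fit$objective, 0),
    threshold = vapply(model$classifiers, `[[`, 0, "threshold"),
    training_accuracy = vapply(model$classifiers, `[[`, 0, "training_accuracy"),
    row.names = NULL)
  utils::write.csv(report, file.path(config$model_dir, "training_report.csv"),
                   row.names = FALSE)
  say(config, "model written to %s (%d classifiers)", config$model_dir,
      length(model$classifiers))
  invisible(model)
}

#' Predict crowns from a persisted model
#'
#' Loads the model directory, reads and band-filters the test table, runs
#' one-vs-one (or hierarchical) voting and writes a predictions CSV with
#' bag id, predicted labels, votes and (optionally epsilon-softened)
#' probabilities. Tie events are reported via the `tie` column.
#'
#' @param config a [run_config()] with `model_dir`, `test_table`, `out` set.
#' @return The `miace_predictions`, invisibly.
#' @export
run_predict <- function(config) {
  model <- read_miace_model(config$model_dir)
  y <- read_instance_table(config$test_table)
  y <- remove_water_bands(y, config$water_band_ranges)
  preds <- if (!is.null(model$hierarchy)) {
    predict_hierarchical(model, y, seed = config$seed)
  } else {
    predict(model, y, seed = config$seed)
  }
  if (!is.null(config$epsilon)) preds <- soften(preds, config$epsilon)
  df <- as.data.frame(preds)
  if (is.null(config$out)) stop("config$out is required")
  utils::write.csv(df, config$out, row.names = FALSE)
  say(config, "wrote %d predictions to %s (%d tie(s))",
      nrow(df), config$out, sum(preds$tie))
  invisible(preds)
}

#' Evaluate predictions against ground truth
#'
#' Computes the confusion matrix, rank-1 accuracy, per-class one-vs-rest
#' metrics and — when probabilities are finite on the true class — the cross
#' entropy, writing `confusion.csv`, `per_class_metrics.csv` and
#' `summary.txt` under `config$out`.
#'
#' @param preds a `miace_predictions` object (e.g. from [run_predict()]).
#' @param config a [run_config()] with `out` set (a directory).
#' @return List with `confusion`, `accuracy`, `per_class`, `cross_entropy`
#'   (NA if probabilities are crisp and imperfect), invisibly.
#' @export
run_evaluate <- function(preds, config) {
  cm <- confusion_matrix(preds)
  acc <- rank1_accuracy(preds)
  pc <- per_class_metrics(cm)
  ce <- tryCatch(cross_entropy(preds), error = function(e) NA_real_)
  dir.create(config$out, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(as.data.frame.matrix(unclass(cm)),
                   file.path(config$out, "confusion.csv"))
  utils::write.csv(pc, file.path(config$out, "per_class_metrics.csv"),
                   row.names = FALSE)
  writeLines(c(sprintf("crowns: %d", length(preds$bag_id)),
               sprintf("rank-1 accuracy: %.4f", acc),
               sprintf("cross entropy: %s",
                       if (is.na(ce)) "undefined (crisp probabilities)"
                       else sprintf("%.4f", ce)),
               sprintf("ties: %d", sum(preds$tie))),
             file.path(config$out, "summary.txt"))
  say(config, "rank-1 accuracy %.4f; report in %s", acc, config$out)
  invisible(list(confusion = cm, accuracy = acc, per_class = pc,
                 cross_entropy = ce))
}

#' Cross-validate from a config
#'
#' Loads and preprocesses the training table and runs
#' [crossval_ovo()] at the configured level (hierarchical CV is not defined;
#' `level = "hierarchical"` falls back to genus).
#'
#' @param config a [run_config()] with `train_table` set.
#' @return The `miace_cv` result, invisibly (also written to `config$out`
#'   as `cv_confusion.csv` + `cv_summary.txt` when `out` is set).
#' @export
run_cv <- function(config) {
  x <- load_training_set(config)
  level <- if (config$level == "hierarchical") "genus" else config$level
  cv <- crossval_ovo(x, level = level, pairs_mode = config$pairs_mode,
                     repeats = config$cv_repeats, seed = config$seed,
                     lambda = config$lambda, max_iter = config$max_iter)
  if (!is.null(config$out)) {
    dir.create(config$out, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(as.data.frame.matrix(cv$mean_confusion),
                     file.path(config$out, "cv_confusion.csv"))
    writeLines(c(sprintf("repeats: %d", cv$repeats),
                 sprintf("mean rank-1 accuracy: %.4f", cv$accuracy)),
               file.path(config$out, "cv_summary.txt"))
  }
  say(config, "CV mean rank-1 accuracy %.4f over %d repeats",
      cv$accuracy, cv$repeats)
  invisible(cv)
}

#' Simulate bags from a config and write them as an instance table
#'
#' @param synth a [synth_config()] (or `NULL` for defaults).
#' @param config a [run_config()] with `out` set (CSV path); the ground
#'   truth side file is written next to it as `<out>_ground_truth.csv`.
#' @return The simulated `bag_set`, invisibly.
#' @export
run_simulate <- function(config, synth = synth_config()) {
  x <- simulate_bags(synth)
  if (is.null(config$out)) stop("config$out is required")
  write_instance_table(x, config$out)
  utils::write.csv(attr(x, "ground_truth"),
                   paste0(sub("\\.csv$", "", config$out), "_ground_truth.csv"),
                   row.names = FALSE)
  say(config, "wrote %d crowns / %d pixels to %s",
      n_bags(x), n_instances(x), config$out)
  invisible(x)
}
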