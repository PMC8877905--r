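# Pair classifier training, evaluation and prediction.
#
# The neural network is the package's own MLP (see mlp.R); the baseline
# algorithms are thin wrappers over randomForest, e1071::svm and
# xgboost with hyperparameters pinned in inst/extdata/model_defaults.json
# so model comparisons are reproducible.

MODEL_ALGORITHMS <- c("ann", "random_forest", "svm", "gradient_boosting")

.model_defaults <- function() {
  path <- system.file("extdata", "model_defaults.json", package = "coscreen")
  jsonlite::read_json(path, simplifyVector = TRUE)
}

#' Classifier configuration
#'
#' @param algorithm One of `"ann"` (multilayer perceptron),
#'   `"random_forest"`, `"svm"`, `"gradient_boosting"`.
#' @param hyperparameters Named list overriding the shipped defaults for
#'   the chosen algorithm.
#' @param seed Integer seed; all randomness in training flows from it.
#' @param decision_threshold Probability cutoff for the positive call,
#'   in (0, 1).
#' @param pair_mode Pair featurization mode, `"concat"` or
#'   `"symmetric"` (see [featurize_pair()]).
#' @return A `model_config` list.
#' @export
model_config <- function(algorithm = c("ann", "random_forest", "svm",
                                       "gradient_boosting"),
                         hyperparameters = list(), seed = 1L,
                         decision_threshold = 0.5,
                         pair_mode = c("concat", "symmetric")) {
  algorithm <- match.arg(algorithm)
  pair_mode <- match.arg(pair_mode)
  if (decision_threshold <= 0 || decision_threshold >= 1) {
    stop("`decision_threshold` must be in (0, 1)", call. = FALSE)
  }
  hp <- .model_defaults()[[algorithm]]
  hp[names(hyperparameters)] <- hyperparameters
  structure(list(algorithm = algorithm, hyperparameters = hp,
                 seed = as.integer(seed),
                 decision_threshold = decision_threshold,
                 pair_mode = pair_mode),
            class = "model_config")
}

#' Train a pair classifier
#'
#' Featurizes the labeled pairs against the cleaned descriptor matrix
#' and fits the configured algorithm. The descriptor schema (and, when
#' supplied, the fitted cleaning transform) is frozen into the model so
#' screening panels are transformed identically at prediction time.
#'
#' @param pairs Labeled `pair_table` with both classes present.
#' @param dmat Cleaned descriptor matrix covering all pair members.
#' @param config A `model_config`.
#' @param clean Optional `clean_report` to freeze into the model.
#' @return An object of class `cocrystal_model`.
#' @export
train_classifier <- function(pairs, dmat, config = model_config(),
                             clean = NULL) {
  if (!"label" %in% names(pairs) || anyNA(pairs$label)) {
    stop("training requires fully labeled pairs", call. = FALSE)
  }
  y <- pairs$label
  if (length(unique(y)) < 2L) {
    stop("training set contains a single class", call. = FALSE)
  }
  x <- featurize_pairs(pairs, dmat, config$pair_mode)
  hp <- config$hyperparameters

  fit <- switch(
    config$algorithm,
    ann = mlp_fit(x, y,
                  hidden = as.integer(unlist(hp$hidden)),
                  dropout = hp$dropout,
                  learning_rate = hp$learning_rate,
                  batch_size = hp$batch_size,
                  max_epochs = hp$max_epochs,
                  patience = hp$patience,
                  val_fraction = hp$val_fraction,
                  seed = config$seed),
    random_forest = with_seed(config$seed,
      randomForest::randomForest(x = x, y = factor(y, levels = c(0, 1)),
                                 ntree = hp$ntree)),
    svm = with_seed(config$seed,
      e1071::svm(x = x, y = factor(y, levels = c(0, 1)),
                 kernel = hp$kernel, cost = hp$cost,
                 probability = TRUE, scale = FALSE)),
    gradient_boosting = with_seed(config$seed,
      xgboost::xgboost(x, factor(y, levels = c(0, 1)),
                       objective = "binary:logistic",
                       nrounds = hp$nrounds,
                       learning_rate = hp$eta,
                       max_depth = hp$max_depth,
                       nthreads = 1L, seed = config$seed,
                       verbosity = 0))
  )

  structure(list(fit = fit, config = config,
                 feature_names = colnames(x),
                 schema = colnames(dmat),
                 clean = clean),
            class = "cocrystal_model")
}

#' @export
print.cocrystal_model <- function(x, ...) {
  cat("Cocrystal pair classifier\n")
  cat("  algorithm:", x$config$algorithm, "\n")
  cat("  features: ", length(x$feature_names), "\n")
  cat("  threshold:", x$config$decision_threshold, "\n")
  invisible(x)
}

#' Predict cocrystal probabilities for pairs
#'
#' @param model A `cocrystal_model`.
#' @param pairs A `pair_table` (labels optional).
#' @param dmat Descriptor matrix on the model's cleaned schema.
#' @return The pair table with `probability` and `predicted` columns
#'   (`predicted = 1` iff probability >= the configured threshold).
#' @export
predict_pairs <- function(model, pairs, dmat) {
  stopifnot(inherits(model, "cocrystal_model"))
  if (!identical(colnames(dmat), model$schema)) {
    stop("descriptor schema mismatch with trained model; differing columns: ",
         paste(union(setdiff(colnames(dmat), model$schema),
                     setdiff(model$schema, colnames(dmat))), collapse = ", "),
         call. = FALSE)
  }
  x <- featurize_pairs(pairs, dmat, model$config$pair_mode)
  prob <- switch(
    model$config$algorithm,
    ann = predict(model$fit, x),
    random_forest = predict(model$fit, x, type = "prob")[, "1"],
    svm = {
      pr <- predict(model$fit, x, probability = TRUE)
      attr(pr, "probabilities")[, "1"]
    },
    gradient_boosting = predict(model$fit, x, type = "response")
  )
  out <- as.data.frame(pairs)
  out$probability <- as.numeric(prob)
  out$predicted <- as.integer(out$probability >= model$config$decision_threshold)
  out
}

#' Classification metrics from labels and predictions
#'
#' Computes the confusion matrix and the three headline metrics used in
#' cocrystal virtual screening: accuracy, recall of the positive
#' ("success") label, and F1 (with positive-class precision reported as
#' well). Degenerate cases follow the conventions precision = 0 when no
#' positive call is made and F1 = 0 when precision + recall = 0.
#'
#' @param label 0/1 truth vector.
#' @param predicted 0/1 prediction vector.
#' @return An `eval_metrics` list: `accuracy`, `recall_positive`,
#'   `precision_positive`, `f1`, `confusion` (TP, FP, FN, TN).
#' @export
eval_metrics <- function(label, predicted) {
  stopifnot(length(label) == length(predicted), length(label) > 0L)
  label <- as.integer(label); predicted <- as.integer(predicted)
  tp <- sum(label == 1L & predicted == 1L)
  fp <- sum(label == 0L & predicted == 1L)
  fn <- sum(label == 1L & predicted == 0L)
  tn <- sum(label == 0L & predicted == 0L)
  accuracy <- (tp + tn) / (tp + fp + fn + tn)
  recall <- if (tp + fn > 0L) tp / (tp + fn) else 0
  precision <- if (tp + fp > 0L) tp / (tp + fp) else 0
  f1 <- if (precision + recall > 0) 2 * precision * recall / (precision + recall) else 0
  structure(list(accuracy = accuracy, recall_positive = recall,
                 precision_positive = precision, f1 = f1,
                 confusion = c(TP = tp, FP = fp, FN = fn, TN = tn)),
            class = "eval_metrics")
}

#' @export
print.eval_metrics <- function(x, ...) {
  cat(sprintf("accuracy %.3f | recall+ %.3f | precision+ %.3f | F1 %.3f\n",
              x$accuracy, x$recall_positive, x$precision_positive, x$f1))
  cat("confusion:", paste(names(x$confusion), x$confusion, collapse = "  "), "\n")
  invisible(x)
}

#' Evaluate a trained model on a labeled test set
#'
#' @param model A `cocrystal_model`.
#' @param pairs Labeled `pair_table`.
#' @param dmat Descriptor matrix on the model's schema.
#' @return An `eval_metrics` object.
#' @export
evaluate <- function(model, pairs, dmat) {
  if (nrow(pairs) == 0L) stop("empty test set", call. = FALSE)
  if (!"label" %in% names(pairs) || anyNA(pairs$label)) {
    stop("evaluation requires labeled pairs", call. = FALSE)
  }
  pred <- predict_pairs(model, pairs, dmat)
  eval_metrics(pred$label, pred$predicted)
}

#' Compare classifier configurations on one shared split
#'
#' Trains every configuration on the same stratified train/test split
#' and tabulates the evaluation metrics, sorted by F1 (descending).
#'
#' @param pairs Labeled `pair_table`.
#' @param dmat Cleaned descriptor matrix.
#' @param configs List of `model_config` objects (at least 2).
#' @param test_fraction Held-out fraction for the shared split.
#' @param seed Seed for the shared split.
#' @return Data.frame with columns `algorithm`, `accuracy`,
#'   `recall_positive`, `precision_positive`, `f1`.
#' @export
compare_models <- function(pairs, dmat, configs, test_fraction = 0.2,
                           seed = 1L) {
  if (length(configs) < 2L) stop("need at least 2 configs", call. = FALSE)
  sp <- split_dataset(pairs, test_fraction, seed)
  rows <- lapply(configs, function(cfg) {
    m <- train_classifier(sp$train, dmat, cfg)
    met <- evaluate(m, sp$test, dmat)
    data.frame(algorithm = cfg$algorithm,
               accuracy = met$accuracy,
               recall_positive = met$recall_positive,
               precision_positive = met$precision_positive,
               f1 = met$f1,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$f1), , drop = FALSE]
  rownames(out) <- NULL
  out
}
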