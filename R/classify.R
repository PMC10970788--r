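# The three fingerprint classifiers under one prediction contract:
# a multilayer perceptron trained in-package (softmax cross-entropy, Adam,
# dropout, patience-based early stopping), an RBF support vector machine
# (e1071) and a random forest (ranger).
#
# A trained model is a `green_classifier` object; `predict_scores()` returns
# the probability of the green class in [0, 1] and `predict_labels()`
# thresholds it at 0.5.

#' MLP hyperparameter configuration
#'
#' Defaults follow the reference architecture: 2048-bit fingerprint input,
#' two hidden layers of 256 units with ReLU and dropout 0.1, a 2-unit
#' softmax output, cross-entropy loss, Adam at learning rate 0.001, batches
#' of 1/16 of the training set, and early stopping after 7 epochs without
#' improvement of the mean training loss (improvement = decrease of more
#' than `1e-6` below the running best). `max_epochs` is a safety bound.
#'
#' @param hidden Integer vector of hidden-layer widths.
#' @param dropout Dropout probability between layers.
#' @param learning_rate Adam learning rate.
#' @param batch_fraction Batch size as a fraction of the training set.
#' @param early_stop_patience Number of non-improving epochs tolerated.
#' @param max_epochs Hard epoch cap.
#' @param seed Integer seed controlling initialization and batch order.
#' @return A list of class `mlp_config`.
#' @export
mlp_config <- function(hidden = c(256, 256), dropout = 0.1,
                       learning_rate = 0.001, batch_fraction = 1 / 16,
                       early_stop_patience = 7, max_epochs = 500, seed = 1) {
  stopifnot(all(hidden > 0), dropout >= 0, dropout < 1,
            learning_rate > 0, batch_fraction > 0, batch_fraction <= 1,
            early_stop_patience >= 1, max_epochs >= 1)
  structure(list(hidden = as.integer(hidden), dropout = dropout,
                 learning_rate = learning_rate,
                 batch_fraction = batch_fraction,
                 early_stop_patience = as.integer(early_stop_patience),
                 max_epochs = as.integer(max_epochs),
                 seed = as.integer(seed)),
            class = "mlp_config")
}

#' SVM hyperparameter configuration (RBF kernel)
#'
#' @param C Soft-margin cost (default 1).
#' @param gamma RBF kernel width (default 0.1).
#' @param seed Seed for the internal probability-calibration fold split.
#' @return A list of class `svm_config`.
#' @export
svm_config <- function(C = 1, gamma = 0.1, seed = 1) {
  stopifnot(C > 0, gamma > 0)
  structure(list(C = C, gamma = gamma, seed = as.integer(seed)),
            class = "svm_config")
}

#' Random forest hyperparameter configuration
#'
#' Defaults mirror the reference model: 100 trees of depth at most 6,
#' `floor(log2(p))` candidate features per split, and terminal nodes of at
#' least 50 samples.
#'
#' @param n_estimators Number of trees.
#' @param max_depth Maximum tree depth.
#' @param min_samples_leaf Minimum terminal-node size.
#' @param max_features `"log2"` (the only supported policy) or an integer.
#' @param seed Integer seed.
#' @return A list of class `rf_config`.
#' @export
rf_config <- function(n_estimators = 100, max_depth = 6,
                      min_samples_leaf = 50, max_features = "log2", seed = 1) {
  stopifnot(n_estimators >= 1, max_depth >= 1, min_samples_leaf >= 1)
  structure(list(n_estimators = as.integer(n_estimators),
                 max_depth = as.integer(max_depth),
                 min_samples_leaf = as.integer(min_samples_leaf),
                 max_features = max_features, seed = as.integer(seed)),
            class = "rf_config")
}

.check_training_input <- function(X, y, min_n = 2) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  colnames(X) <- paste0("bit", seq_len(ncol(X)))  # ranger needs covariate names
  y <- as.character(y)
  stopifnot(nrow(X) == length(y))
  if (length(unique(y)) < 2) stop2("training labels contain a single class")
  if (!all(y %in% .LABEL_LEVELS)) {
    stop2("labels must be 'green'/'nongreen' (got: %s)",
          paste(utils::head(setdiff(unique(y), .LABEL_LEVELS)), collapse = ", "))
  }
  if (nrow(X) < min_n) stop2("need at least %d training samples", min_n)
  list(X = X, y = y)
}

.new_classifier <- function(kind, fit, config, log = list()) {
  structure(list(kind = kind, fit = fit, config = config, log = log),
            class = "green_classifier")
}

#' Train the multilayer perceptron
#'
#' Architecture `p -> hidden[1] -> hidden[2] -> 2` with ReLU activations and
#' dropout between layers, softmax cross-entropy loss, Adam updates, batch
#' size `ceil(n * batch_fraction)`. Training halts when the epoch-mean
#' training loss has failed to improve its running best `patience` times in
#' a row, or at `max_epochs`. Fully deterministic given `cfg$seed`.
#'
#' @param X Numeric matrix of fingerprints (rows = molecules).
#' @param y Character labels ("green"/"nongreen"); green is the positive
#'   class.
#' @param cfg An [mlp_config()].
#' @return A `green_classifier`.
#' @export
train_mlp <- function(X, y, cfg = mlp_config()) {
  inp <- .check_training_input(X, y, min_n = 16)
  X <- inp$X; y <- inp$y
  n <- nrow(X)
  target <- cbind(nongreen = as.numeric(y == "nongreen"),
                  green = as.numeric(y == "green"))
  batch <- max(1L, ceiling(n * cfg$batch_fraction))
  fit <- mlp_train_cpp(X, target, cfg$hidden, cfg$dropout, cfg$learning_rate,
                       batch, cfg$early_stop_patience, cfg$max_epochs,
                       cfg$seed, 1e-6)
  .new_classifier("mlp", fit, cfg,
                  log = list(epoch_loss = fit$epoch_loss, epochs = fit$epochs))
}

.mlp_forward <- function(fit, X) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  mlp_forward_cpp(X, fit$W, fit$b)
}

#' Train the RBF support vector machine
#'
#' @param X,y As in [train_mlp()].
#' @param cfg An [svm_config()].
#' @return A `green_classifier` with Platt-scaled probability outputs.
#' @export
train_svm <- function(X, y, cfg = svm_config()) {
  inp <- .check_training_input(X, y)
  fit <- with_local_seed(cfg$seed, {
    e1071::svm(x = inp$X, y = factor(inp$y, levels = .LABEL_LEVELS),
               kernel = "radial", cost = cfg$C, gamma = cfg$gamma,
               probability = TRUE, scale = FALSE)
  })
  .new_classifier("svm", fit, cfg)
}

#' Train the random forest
#'
#' @param X,y As in [train_mlp()].
#' @param cfg An [rf_config()].
#' @return A `green_classifier` with out-of-the-box class probabilities.
#' @export
train_rf <- function(X, y, cfg = rf_config()) {
  inp <- .check_training_input(X, y)
  mtry <- if (identical(cfg$max_features, "log2")) {
    max(1L, floor(log2(ncol(inp$X))))
  } else as.integer(cfg$max_features)
  fit <- ranger::ranger(
    x = inp$X, y = factor(inp$y, levels = .LABEL_LEVELS),
    num.trees = cfg$n_estimators, mtry = mtry,
    min.node.size = cfg$min_samples_leaf, max.depth = cfg$max_depth,
    probability = TRUE, seed = cfg$seed, num.threads = 1
  )
  .new_classifier("rf", fit, cfg)
}

#' Green-class probability scores
#'
#' Generic so that the evaluation harness accepts any classifier honouring
#' the contract (scores in `[0, 1]`, green = positive class), not only the
#' three built-in model families.
#'
#' @param object A trained classifier.
#' @param X Fingerprint matrix.
#' @return Numeric vector of green-class probabilities in `[0, 1]`.
#' @export
predict_scores <- function(object, X) UseMethod("predict_scores")

#' @rdname predict_scores
#' @export
predict_scores.green_classifier <- function(object, X) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  colnames(X) <- paste0("bit", seq_len(ncol(X)))
  scores <- switch(
    object$kind,
    mlp = .mlp_forward(object$fit, X)[, 2],
    svm = {
      pr <- stats::predict(object$fit, X, probability = TRUE)
      attr(pr, "probabilities")[, "green"]
    },
    rf = stats::predict(object$fit, data = X, num.threads = 1)$predictions[, "green"],
    stop2("unknown classifier kind '%s'", object$kind)
  )
  unname(pmin(pmax(scores, 0), 1))
}

#' Thresholded class labels
#'
#' @param object A `green_classifier`.
#' @param X Fingerprint matrix.
#' @param threshold Score cutoff (default 0.5).
#' @return Character vector "green"/"nongreen", consistent with
#'   [predict_scores()] at the threshold.
#' @export
predict_labels <- function(object, X, threshold = 0.5) {
  ifelse(predict_scores(object, X) >= threshold, "green", "nongreen")
}

#' @export
print.green_classifier <- function(x, ...) {
  cat(sprintf("<green_classifier: %s>\n", x$kind))
  if (!is.null(x$log$epochs)) cat(sprintf("  epochs trained: %d\n", x$log$epochs))
  invisible(x)
}

#' Grid search by k-fold cross-validated accuracy
#'
#' Scores every parameter combination with stratified k-fold accuracy and
#' returns the first-listed maximiser (ties broken by grid order) plus the
#' full score table for audit. A candidate whose training fails is scored
#' `-Inf` and noted in the table.
#'
#' @param model_family One of "svm", "rf", "mlp".
#' @param param_grid A data.frame of candidate parameter combinations (one
#'   row each, e.g. from [expand.grid()]), or a list of named lists.
#' @param X,y Training data as in [train_mlp()].
#' @param k Folds (default 5).
#' @param seed Seed for the fold split.
#' @return A list with `best_params`, `best_score` and `table`.
#' @export
grid_search <- function(model_family, param_grid, X, y, k = 5, seed = 1) {
  model_family <- match.arg(model_family, c("svm", "rf", "mlp"))
  if (is.data.frame(param_grid)) {
    if (nrow(param_grid) == 0) stop2("empty parameter grid")
    cands <- lapply(seq_len(nrow(param_grid)), function(i) {
      as.list(param_grid[i, , drop = FALSE])
    })
  } else {
    if (length(param_grid) == 0) stop2("empty parameter grid")
    cands <- param_grid
  }
  inp <- .check_training_input(X, y)
  folds <- make_cv_splits(inp$y, k = k, repeats = 1, seed = seed)[[1]]
  ctor <- switch(model_family,
                 svm = function(par) do.call(svm_config, par),
                 rf = function(par) do.call(rf_config, par),
                 mlp = function(par) do.call(mlp_config, par))
  trainer <- switch(model_family, svm = train_svm, rf = train_rf, mlp = train_mlp)
  scores <- numeric(length(cands))
  notes <- character(length(cands))
  for (i in seq_along(cands)) {
    acc <- tryCatch({
      cfg <- ctor(cands[[i]])
      mean(vapply(seq_len(k), function(f) {
        tr <- folds != f
        m <- trainer(inp$X[tr, , drop = FALSE], inp$y[tr], cfg)
        mean(predict_labels(m, inp$X[!tr, , drop = FALSE]) == inp$y[!tr])
      }, 0))
    }, error = function(e) { notes[i] <<- conditionMessage(e); -Inf })
    scores[i] <- acc
  }
  best <- which.max(scores)
  tab <- data.frame(candidate = seq_along(cands),
                    mean_cv_accuracy = scores, note = notes,
                    stringsAsFactors = FALSE)
  tab$params <- vapply(cands, function(p) {
    paste(names(p), unlist(p), sep = "=", collapse = ", ")
  }, "")
  list(best_params = cands[[best]], best_score = scores[best], table = tab)
}

#' Save / load a trained classifier
#'
#' Serializes the model (configuration plus fitted parameters) to a single
#' file.
#'
#' @param object A `green_classifier`.
#' @param path File path.
#' @return `save_classifier` invisibly returns the path; `load_classifier`
#'   returns the `green_classifier`.
#' @export
save_classifier <- function(object, path) {
  stopifnot(inherits(object, "green_classifier"))
  saveRDS(object, path)
  invisible(path)
}

#' @rdname save_classifier
#' @export
load_classifier <- function(path) {
  obj <- readRDS(path)
  if (!inherits(obj, "green_classifier")) stop2("%s is not a saved classifier", path)
  obj
}
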