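# Binary-classification metrics and the repeated stratified
# cross-validation harness. Green is the positive class throughout.

#' Confusion counts
#'
#' @param y_true,y_pred Character vectors of "green"/"nongreen" labels (or
#'   anything coercible where green is the positive class via
#'   [normalize_label()] semantics: values already equal to "green" count
#'   as positive).
#' @return A list of class `confusion_counts` with integer fields `TP`,
#'   `TN`, `FP`, `FN`.
#' @export
#' @examples
#' confusion(c("green", "nongreen"), c("green", "green"))
confusion <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred)) {
    stop2("y_true and y_pred differ in length (%d vs %d)",
          length(y_true), length(y_pred))
  }
  tp <- sum(y_true == "green" & y_pred == "green")
  tn <- sum(y_true == "nongreen" & y_pred == "nongreen")
  fp <- sum(y_true == "nongreen" & y_pred == "green")
  fn <- sum(y_true == "green" & y_pred == "nongreen")
  structure(list(TP = tp, TN = tn, FP = fp, FN = fn),
            class = "confusion_counts")
}

#' Confusion counts from raw integers
#' @param TP,TN,FP,FN Non-negative integers.
#' @return A `confusion_counts` object.
#' @export
confusion_counts <- function(TP, TN, FP, FN) {
  stopifnot(TP >= 0, TN >= 0, FP >= 0, FN >= 0)
  structure(list(TP = TP, TN = TN, FP = FP, FN = FN),
            class = "confusion_counts")
}

.safe_ratio <- function(num, den, what) {
  if (den == 0) {
    warn2("%s undefined (zero denominator); returning 0", what)
    return(0)
  }
  num / den
}

#' Precision: TP / (TP + FP)
#' @param c A `confusion_counts` object.
#' @return A number in `[0, 1]`; 0 with a warning if the denominator is 0.
#' @export
precision <- function(c) .safe_ratio(c$TP, c$TP + c$FP, "precision")

#' Accuracy: (TP + TN) / (TP + TN + FP + FN)
#' @inheritParams precision
#' @return A number in `[0, 1]`.
#' @export
accuracy <- function(c) .safe_ratio(c$TP + c$TN, c$TP + c$TN + c$FP + c$FN, "accuracy")

#' Recall: TP / (TP + FN)
#' @inheritParams precision
#' @return A number in `[0, 1]`.
#' @export
recall <- function(c) .safe_ratio(c$TP, c$TP + c$FN, "recall")

#' F1: 2 TP / (2 TP + FN + FP)
#' @inheritParams precision
#' @return A number in `[0, 1]`.
#' @export
f1 <- function(c) .safe_ratio(2 * c$TP, 2 * c$TP + c$FN + c$FP, "F1")

#' Matthews correlation coefficient
#'
#' `(TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`; defined as 0
#' (with a warning) when any factor of the denominator is 0.
#'
#' @inheritParams precision
#' @return A number in `[-1, 1]`.
#' @export
mcc <- function(c) {
  fac <- c(c$TP + c$FP, c$TP + c$FN, c$TN + c$FP, c$TN + c$FN)
  if (any(fac == 0)) {
    warn2("MCC undefined (zero denominator factor); returning 0")
    return(0)
  }
  fac <- as.numeric(fac)   # avoid integer overflow in the product
  (as.numeric(c$TP) * c$TN - as.numeric(c$FP) * c$FN) / sqrt(prod(fac))
}

#' Area under the ROC curve by pair counting
#'
#' The probability that a uniformly chosen positive sample receives a
#' higher score than a uniformly chosen negative one, ties counted half:
#' `(#{pos > neg} + 0.5 #{ties}) / (#pos * #neg)`, computed via midranks
#' (the Mann-Whitney statistic).
#'
#' @param y_true Character labels; "green" is positive.
#' @param scores Numeric scores, higher = more green.
#' @return AUC in `[0, 1]`.
#' @export
auc <- function(y_true, scores) {
  stopifnot(length(y_true) == length(scores))
  pos <- y_true == "green"
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0) stop2("AUC needs both classes present")
  r <- rank(scores, ties.method = "average")
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Average precision (step-wise, non-interpolated)
#'
#' `AP = sum_k (R_k - R_{k-1}) P_k` over the descending-score ranking,
#' where `P_k`, `R_k` are precision and recall after the k-th prediction.
#' Tied scores are ranked in input order.
#'
#' @inheritParams auc
#' @return AP in `(0, 1]`.
#' @export
average_precision <- function(y_true, scores) {
  stopifnot(length(y_true) == length(scores))
  pos <- y_true == "green"
  if (!any(pos) || all(pos)) stop2("average precision needs both classes present")
  ord <- order(scores, decreasing = TRUE)
  hits <- cumsum(pos[ord])
  prec_at_k <- hits / seq_along(hits)
  sum(prec_at_k[pos[ord]]) / sum(pos)
}

#' Metrics of one evaluated fold
#' @param y_true,y_pred,scores Truth, thresholded predictions, and scores.
#' @return Named numeric vector with the confusion counts and all seven
#'   metrics.
#' @export
fold_metrics <- function(y_true, y_pred, scores) {
  cc <- confusion(y_true, y_pred)
  c(TP = cc$TP, TN = cc$TN, FP = cc$FP, FN = cc$FN,
    precision = precision(cc), accuracy = accuracy(cc), recall = recall(cc),
    f1 = f1(cc), mcc = mcc(cc),
    auc = auc(y_true, scores), average_precision = average_precision(y_true, scores))
}

#' Repeated stratified cross-validation of a classifier
#'
#' Runs the k-fold x repeats evaluation: for every fold of every repeat the
#' model is trained on the remaining folds and scored on the held-out fold.
#' The report aggregates all folds (mean and standard deviation per metric)
#' and averages the per-fold confusion matrices element-wise. A fold whose
#' training fails is recorded and excluded from the means.
#'
#' @param X Fingerprint matrix.
#' @param y Labels ("green"/"nongreen").
#' @param model_factory Function `(X_train, y_train, fold_seed)` returning a
#'   `green_classifier` (or any object honouring [predict_scores()]).
#' @param k,repeats,seed Cross-validation scheme (defaults 5, 10).
#' @return A list of class `metric_report`: `per_fold` data.frame,
#'   `summary` (mean/sd per metric), `mean_confusion` 2x2 matrix,
#'   `failed` data.frame of failed folds.
#' @export
run_repeated_cv <- function(X, y, model_factory, k = 5, repeats = 10, seed = 1) {
  X <- as.matrix(X)
  y <- as.character(y)
  splits <- make_cv_splits(y, k = k, repeats = repeats, seed = seed)
  rows <- list()
  failures <- list()
  metric_names <- c("precision", "accuracy", "recall", "f1", "mcc",
                    "auc", "average_precision")
  for (r in seq_along(splits)) {
    fold <- splits[[r]]
    for (f in seq_len(k)) {
      test <- fold == f
      fold_seed <- derive_seed(seed, sprintf("fold-%d-%d", r, f))
      res <- tryCatch({
        model <- model_factory(X[!test, , drop = FALSE], y[!test], fold_seed)
        sc <- predict_scores(model, X[test, , drop = FALSE])
        pred <- ifelse(sc >= 0.5, "green", "nongreen")
        fold_metrics(y[test], pred, sc)
      }, error = function(e) e)
      if (inherits(res, "error")) {
        failures[[length(failures) + 1]] <-
          data.frame(repeat_ = r, fold = f, error = conditionMessage(res))
      } else {
        rows[[length(rows) + 1]] <-
          data.frame(repeat_ = r, fold = f, n = sum(test), t(res))
      }
    }
  }
  if (!length(rows)) stop2("every fold failed; no metrics to report")
  per_fold <- do.call(rbind, rows)
  summary <- data.frame(
    metric = metric_names,
    mean = vapply(metric_names, function(m) mean(per_fold[[m]]), 0),
    sd = vapply(metric_names, function(m) stats::sd(per_fold[[m]]), 0),
    row.names = NULL
  )
  mean_conf <- matrix(
    c(mean(per_fold$TP), mean(per_fold$FN),
      mean(per_fold$FP), mean(per_fold$TN)),
    2, 2, byrow = TRUE,
    dimnames = list(true = c("green", "nongreen"),
                    predicted = c("green", "nongreen"))
  )
  structure(list(per_fold = per_fold, summary = summary,
                 mean_confusion = mean_conf,
                 failed = if (length(failures)) do.call(rbind, failures) else NULL,
                 scheme = list(k = k, repeats = repeats, seed = seed)),
            class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat(sprintf("<metric_report: %d folds (%d x %d CV)>\n",
              nrow(x$per_fold), x$scheme$k, x$scheme$repeats))
  s <- x$summary
  for (i in seq_len(nrow(s))) {
    cat(sprintf("  %-18s %.4f +/- %.4f\n", s$metric[i], s$mean[i], s$sd[i]))
  }
  cat("  mean confusion (rows = truth green/nongreen):\n")
  print(round(x$mean_confusion, 2))
  if (!is.null(x$failed)) cat(sprintf("  failed folds: %d\n", nrow(x$failed)))
  invisible(x)
}

#' Export a metric report as CSV files
#'
#' Writes the per-fold long table (`repeat`, `fold`, `metric`, `value`),
#' the mean/sd summary, and the 2x2 mean confusion matrix.
#'
#' @param report A `metric_report`.
#' @param dir Output directory (created if needed).
#' @param prefix File-name prefix.
#' @return Invisibly, the paths written.
#' @export
write_metric_report <- function(report, dir, prefix = "cv") {
  stopifnot(inherits(report, "metric_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  metric_names <- report$summary$metric
  long <- do.call(rbind, lapply(metric_names, function(m) {
    data.frame(repeat_ = report$per_fold$repeat_, fold = report$per_fold$fold,
               metric = m, value = report$per_fold[[m]])
  }))
  long$value <- sprintf("%.6f", long$value)
  p1 <- file.path(dir, paste0(prefix, "_folds.csv"))
  p2 <- file.path(dir, paste0(prefix, "_summary.csv"))
  p3 <- file.path(dir, paste0(prefix, "_mean_confusion.csv"))
  utils::write.csv(long, p1, row.names = FALSE, quote = FALSE)
  summ <- report$summary
  summ$mean <- sprintf("%.6f", summ$mean)
  summ$sd <- sprintf("%.6f", summ$sd)
  utils::write.csv(summ, p2, row.names = FALSE, quote = FALSE)
  utils::write.csv(round(report$mean_confusion, 6), p3, quote = FALSE)
  invisible(c(p1, p2, p3))
}
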