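test_that("confusion counts partition the samples", {
  cc <- confusion(c("green", "green", "nongreen", "nongreen"),
                  c("green", "green", "nongreen", "nongreen"))
  expect_equal(unlist(cc[c("TP", "TN", "FP", "FN")]),
               c(TP = 2, TN = 2, FP = 0, FN = 0))
  cc2 <- confusion(c("green", "nongreen"), c("green", "green"))
  expect_equal(unlist(cc2[c("TP", "TN", "FP", "FN")]),
               c(TP = 1, TN = 0, FP = 1, FN = 0))
  # random vectors against an element-wise counting loop
  set.seed(1)
  yt <- sample(c("green", "nongreen"), 100, replace = TRUE)
  yp <- sample(c("green", "nongreen"), 100, replace = TRUE)
  cc3 <- confusion(yt, yp)
  tp <- tn <- fp <- fn <- 0
  for (i in 1:100) {
    if (yt[i] == "green" && yp[i] == "green") tp <- tp + 1
    else if (yt[i] == "nongreen" && yp[i] == "nongreen") tn <- tn + 1
    else if (yt[i] == "nongreen" && yp[i] == "green") fp <- fp + 1
    else fn <- fn + 1
  }
  expect_equal(unlist(cc3[c("TP", "TN", "FP", "FN")]),
               c(TP = tp, TN = tn, FP = fp, FN = fn))
  expect_equal(tp + tn + fp + fn, 100)
  expect_error(confusion(c("green"), c("green", "green")), "length")
})

test_that("the five metric formulas reproduce hand substitution", {
  perfect <- confusion_counts(50, 50, 0, 0)
  for (f in list(precision, accuracy, recall, f1, mcc)) {
    expect_equal(f(perfect), 1)
  }
  coin <- confusion_counts(25, 25, 25, 25)
  expect_equal(mcc(coin), 0)
  expect_equal(accuracy(coin), 0.5)
  c3 <- confusion_counts(40, 35, 10, 15)
  expect_equal(precision(c3), 0.8)
  expect_equal(accuracy(c3), 0.75)
  expect_equal(recall(c3), 40 / 55)
  expect_equal(f1(c3), 80 / 105)
  expect_equal(mcc(c3), (40 * 35 - 10 * 15) /
                 sqrt((40 + 10) * (40 + 15) * (35 + 10) * (35 + 15)))
})

test_that("zero denominators degrade to 0 with a warning instead of crashing", {
  none_pred_pos <- confusion_counts(0, 50, 0, 50)
  expect_warning(p <- precision(none_pred_pos), "undefined")
  expect_equal(p, 0)
  expect_warning(m <- mcc(none_pred_pos), "undefined")
  expect_equal(m, 0)
})

test_that("f1 equals the precision-recall harmonic mean where both are defined", {
  set.seed(2)
  for (i in 1:50) {
    cc <- confusion_counts(sample(0:30, 1) + 1, sample(0:30, 1),
                           sample(0:30, 1), sample(0:30, 1))
    pr <- precision(cc); rc <- recall(cc)
    if (pr + rc > 0) {
      expect_equal(f1(cc), 2 * pr * rc / (pr + rc), tolerance = 1e-12)
    }
  }
})

test_that("MCC flips sign when predictions are inverted", {
  set.seed(3)
  for (i in 1:20) {
    yt <- sample(c("green", "nongreen"), 60, replace = TRUE)
    yp <- sample(c("green", "nongreen"), 60, replace = TRUE)
    flip <- ifelse(yp == "green", "nongreen", "green")
    m1 <- suppressWarnings(mcc(confusion(yt, yp)))
    m2 <- suppressWarnings(mcc(confusion(yt, flip)))
    expect_equal(m1, -m2, tolerance = 1e-12)
  }
})

test_that("AUC equals exhaustive pair counting and is rank-invariant", {
  y <- c(rep("green", 5), rep("nongreen", 5))
  expect_equal(auc(y, c(6:10, 1:5)), 1)
  expect_equal(auc(y, rep(1, 10)), 0.5)
  set.seed(4)
  for (i in 1:20) {
    s <- sample(1:6, 10, replace = TRUE) + stats::runif(10) * (i %% 2)
    expect_equal(auc(y, s), oracle_auc(y, s), tolerance = 1e-12)
    # strictly monotone transform leaves AUC unchanged
    expect_equal(auc(y, exp(s / 3)), auc(y, s), tolerance = 1e-12)
  }
  expect_error(auc(rep("green", 5), 1:5), "both classes")
})

test_that("average precision matches the step-sum oracle", {
  y <- c(rep("green", 3), rep("nongreen", 7))
  expect_equal(average_precision(y, c(10, 9, 8, 7:1)), 1)
  # single positive ranked worst among n
  y1 <- c("green", rep("nongreen", 9))
  expect_equal(average_precision(y1, c(1, 10:2)), 1 / 10)
  set.seed(5)
  for (i in 1:20) {
    s <- stats::runif(10)
    expect_equal(average_precision(y, s), oracle_ap(y, s), tolerance = 1e-12)
  }
  expect_error(average_precision(rep("green", 4), 1:4), "both classes")
})

test_that("the repeated-CV harness aggregates folds and is model-agnostic", {
  set.seed(6)
  X <- matrix(stats::runif(60 * 8), 60, 8)
  y <- rep(c("green", "nongreen"), each = 30)
  # oracle that memorizes the training labels by storing the full truth
  oracle_factory <- function(Xtr, ytr, seed) {
    structure(list(train = X, y = y), class = "memorizer")
  }
  registerS3method("predict_scores", "memorizer",
                   function(object, X) {
                     idx <- apply(X, 1, function(r) {
                       which.min(colSums((t(object$train) - r)^2))
                     })
                     as.numeric(object$y[idx] == "green")
                   }, envir = asNamespace("greenodor"))
  rep1 <- run_repeated_cv(X, y, oracle_factory, k = 3, repeats = 2, seed = 1)
  expect_true(all(rep1$summary$mean == 1))
  expect_equal(nrow(rep1$per_fold), 6)
  # mean confusion entries sum to the mean fold size
  expect_equal(sum(rep1$mean_confusion), mean(rep1$per_fold$n))
  # constant-positive classifier: accuracy 0.5, recall 1 on a balanced set
  const_factory <- function(Xtr, ytr, seed) structure(list(), class = "alwaysgreen")
  registerS3method("predict_scores", "alwaysgreen",
                   function(object, X) rep(1, nrow(X)),
                   envir = asNamespace("greenodor"))
  rep2 <- suppressWarnings(
    run_repeated_cv(X, y, const_factory, k = 3, repeats = 1, seed = 1))
  s <- rep2$summary
  expect_equal(s$mean[s$metric == "accuracy"], 0.5)
  expect_equal(s$mean[s$metric == "recall"], 1)
})

test_that("failing folds are excluded and recorded, not fatal", {
  X <- matrix(stats::runif(40 * 4), 40, 4)
  y <- rep(c("green", "nongreen"), each = 20)
  flaky <- local({
    calls <- 0
    function(Xtr, ytr, seed) {
      calls <<- calls + 1
      if (calls == 1) stop("synthetic failure")
      structure(list(), class = "alwayshalf")
    }
  })
  registerS3method("predict_scores", "alwayshalf",
                   function(object, X) rep(0.6, nrow(X)),
                   envir = asNamespace("greenodor"))
  rep3 <- suppressWarnings(run_repeated_cv(X, y, flaky, k = 4, repeats = 1, seed = 2))
  expect_equal(nrow(rep3$failed), 1)
  expect_equal(nrow(rep3$per_fold), 3)
  expect_match(rep3$failed$error[1], "synthetic failure")
})

test_that("metric report CSV export writes fold, summary and confusion tables", {
  sp <- generate_separable_fingerprints(30, nbits = 64, seed = 12)
  factory <- function(X, y, seed) train_rf(X, y, rf_config(min_samples_leaf = 2, seed = seed))
  rep <- run_repeated_cv(sp$X, sp$y, factory, k = 3, repeats = 1, seed = 4)
  dir <- withr::local_tempdir()
  paths <- write_metric_report(rep, dir)
  expect_true(all(file.exists(paths)))
  folds <- utils::read.csv(paths[1])
  expect_setequal(unique(folds$metric), rep$summary$metric)
})
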