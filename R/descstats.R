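# Factor-analysis screening of the descriptor battery and the two-sample
# difference analysis between the green and non-green classes.

#' Kaiser-Meyer-Olkin sampling adequacy
#'
#' `KMO = sum r_ij^2 / (sum r_ij^2 + sum q_ij^2)` over off-diagonal
#' entries, where `r` are Pearson correlations and `q` the anti-image
#' partial correlations obtained from the inverse correlation matrix.
#'
#' @param X Numeric matrix/data.frame, observations x variables (at least
#'   3 variables, more observations than variables).
#' @return KMO statistic in `[0, 1]`.
#' @export
kmo <- function(X) {
  X <- as.matrix(X)
  if (ncol(X) < 3) stop2("KMO needs at least 3 variables")
  if (nrow(X) <= ncol(X)) stop2("KMO needs more observations than variables")
  R <- stats::cor(X)
  .check_nonsingular(R)
  Ri <- solve(R)
  d <- 1 / sqrt(diag(Ri))
  Q <- -Ri * outer(d, d)       # anti-image partial correlations
  off <- upper.tri(R)
  sum(R[off]^2) / (sum(R[off]^2) + sum(Q[off]^2))
}

.check_nonsingular <- function(R, tol = 1e-10) {
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < tol) {
    off <- which(abs(R) > 0.9999 & upper.tri(R), arr.ind = TRUE)
    pairs <- if (nrow(off)) {
      paste(apply(off, 1, function(ij) {
        paste(colnames(R)[ij[1]] %||% ij[1], colnames(R)[ij[2]] %||% ij[2], sep = " ~ ")
      }), collapse = "; ")
    } else "no single pair identified"
    stop2("correlation matrix is singular (collinear variables: %s)", pairs)
  }
  invisible(TRUE)
}

#' Bartlett's test of sphericity
#'
#' Tests whether the correlation matrix is the identity:
#' `chi2 = -(n - 1 - (2p + 5)/6) * ln det(R)` on `p(p-1)/2` degrees of
#' freedom.
#'
#' @inheritParams kmo
#' @return A list: `chi2`, `df`, `p_value`.
#' @export
bartlett_sphericity <- function(X) {
  X <- as.matrix(X)
  p <- ncol(X); n <- nrow(X)
  if (p < 3) stop2("Bartlett's test needs at least 3 variables")
  if (n <= p) stop2("Bartlett's test needs more observations than variables")
  R <- stats::cor(X)
  .check_nonsingular(R)
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  chi2 <- max(0, -(n - 1 - (2 * p + 5) / 6) * sum(log(ev)))
  df <- p * (p - 1) / 2
  list(chi2 = chi2, df = df, p_value = stats::pchisq(chi2, df, lower.tail = FALSE))
}

#' Factor analysis by principal-component extraction with varimax rotation
#'
#' Standardizes the variables, extracts `n_factors` components from the
#' correlation matrix, rotates the loading matrix with varimax, and signs
#' each factor so its largest-magnitude loading is positive. The KMO and
#' Bartlett gates are evaluated first (configurable thresholds); failing a
#' gate raises an error unless `enforce_gates = FALSE`, in which case a
#' warning is given.
#'
#' @inheritParams kmo
#' @param n_factors Number of factors to extract (default 3).
#' @param kmo_min Minimum acceptable KMO (default 0.5).
#' @param bartlett_alpha Significance level Bartlett's test must beat
#'   (default 0.05).
#' @param enforce_gates Raise an error on gate failure (default TRUE).
#' @return A list of class `factor_result`: `kmo`, `bartlett_chi2`,
#'   `bartlett_p`, `eigenvalues` (descending, summing to the number of
#'   variables), `loadings` (variables x factors), `n_factors`,
#'   `communalities`.
#' @export
factor_analyze <- function(X, n_factors = 3, kmo_min = 0.5,
                           bartlett_alpha = 0.05, enforce_gates = TRUE) {
  X <- as.matrix(X)
  p <- ncol(X)
  if (n_factors > p) stop2("n_factors (%d) exceeds number of variables (%d)", n_factors, p)
  if (p == 1) {
    return(structure(list(kmo = NA_real_, bartlett_chi2 = NA_real_,
                          bartlett_p = NA_real_, eigenvalues = 1,
                          loadings = matrix(1, 1, 1,
                                            dimnames = list(colnames(X), "F1")),
                          n_factors = 1L, communalities = 1),
                     class = "factor_result"))
  }
  # the gates need the inverse correlation matrix; a singular battery (e.g.
  # duplicated descriptors, which the battery legitimately contains) leaves
  # them undefined but does not prevent principal-component extraction
  gate_err <- NULL
  k <- NA_real_; bt <- list(chi2 = NA_real_, p_value = NA_real_)
  if (p >= 3) {
    res <- tryCatch(list(k = kmo(X), bt = bartlett_sphericity(X)),
                    error = function(e) e)
    if (inherits(res, "error")) gate_err <- conditionMessage(res)
    else { k <- res$k; bt <- res$bt }
  }
  if (p >= 3) {
    fail <- character(0)
    if (!is.null(gate_err)) fail <- sprintf("gates not computable (%s)", gate_err)
    else {
      if (k < kmo_min) fail <- c(fail, sprintf("KMO %.3f < %.2f", k, kmo_min))
      if (bt$p_value > bartlett_alpha) {
        fail <- c(fail, sprintf("Bartlett p %.3g > %.2g", bt$p_value, bartlett_alpha))
      }
    }
    if (length(fail)) {
      msg <- paste("factorability gates failed:", paste(fail, collapse = "; "))
      if (enforce_gates) stop(msg, call. = FALSE) else warning(msg, call. = FALSE)
    }
  }
  R <- stats::cor(X)
  eg <- eigen(R, symmetric = TRUE)
  ev <- eg$values
  L <- eg$vectors[, seq_len(n_factors), drop = FALSE] %*%
    diag(sqrt(pmax(ev[seq_len(n_factors)], 0)), n_factors)
  if (n_factors > 1) L <- .varimax_multistart(L)
  # sign convention: largest |loading| of each factor is positive
  for (j in seq_len(ncol(L))) {
    if (L[which.max(abs(L[, j])), j] < 0) L[, j] <- -L[, j]
  }
  dimnames(L) <- list(colnames(X) %||% paste0("V", seq_len(p)),
                      paste0("F", seq_len(n_factors)))
  structure(list(kmo = k, bartlett_chi2 = bt$chi2, bartlett_p = bt$p_value,
                 eigenvalues = ev, loadings = L, n_factors = as.integer(n_factors),
                 communalities = rowSums(L^2)),
            class = "factor_result")
}

# The varimax iteration can stall in a local optimum (or a saddle, for
# symmetric loading geometries) when started from the unrotated axes, so
# the rotation is restarted from several fixed orthogonal starts and the
# solution with the largest varimax criterion (sum over factors of the
# variance of squared loadings) is kept. Deterministic: starts come from a
# fixed seed.
.varimax_multistart <- function(L, n_starts = 8) {
  m <- ncol(L)
  crit <- function(Z) sum(apply(Z^2, 2, stats::var))
  best <- NULL; best_v <- -Inf
  starts <- with_local_seed(20240101, {
    c(list(diag(m)), lapply(seq_len(n_starts - 1), function(i) {
      qr.Q(qr(matrix(stats::rnorm(m * m), m, m)))
    }))
  })
  for (S in starts) {
    Z <- tryCatch({
      rot <- stats::varimax(L %*% S, normalize = TRUE)
      unclass(rot$loadings)
    }, error = function(e) NULL)
    if (is.null(Z)) next
    v <- crit(Z)
    if (v > best_v) { best_v <- v; best <- Z }
  }
  best %||% L
}

#' @export
print.factor_result <- function(x, ...) {
  cat(sprintf("<factor_result: %d factors, KMO %.3f, Bartlett p %.3g>\n",
              x$n_factors, x$kmo, x$bartlett_p))
  cat("eigenvalues:", paste(sprintf("%.3f", utils::head(x$eigenvalues, 6)),
                            collapse = ", "),
      if (length(x$eigenvalues) > 6) "..." else "", "\n")
  print(round(x$loadings, 3))
  invisible(x)
}

#' Screen descriptors by maximum absolute factor loading
#'
#' Retains the variables whose largest absolute loading across factors is
#' strictly greater than the threshold.
#'
#' @param loadings Variables x factors numeric matrix (or a
#'   `factor_result`).
#' @param loading_threshold Strict threshold (default 0.75).
#' @return Character vector of retained variable names (row names of the
#'   loading matrix).
#' @export
screen_descriptors <- function(loadings, loading_threshold = 0.75) {
  if (inherits(loadings, "factor_result")) loadings <- loadings$loadings
  loadings <- as.matrix(loadings)
  stopifnot(loading_threshold > 0, loading_threshold < 1, all(is.finite(loadings)))
  mx <- apply(abs(loadings), 1, max)
  rn <- rownames(loadings) %||% paste0("V", seq_len(nrow(loadings)))
  rn[mx > loading_threshold]
}

#' Two-sample difference test with normality-gated test selection
#'
#' Decision tree: Shapiro-Wilk on each sample at `alpha`; if either sample
#' rejects normality (or is constant, where Shapiro-Wilk is inapplicable),
#' the two-sided Mann-Whitney U test is used. Otherwise Levene's test
#' (median-centred) decides between Welch's t-test (variances unequal) and
#' the independent t-test. Direction is the sign of
#' `median(x) - median(y)`.
#'
#' @param x,y Numeric samples (each at least 3 values); by convention `x`
#'   is the green class.
#' @param alpha Significance level for the gates and the final call
#'   (default 0.05).
#' @param descriptor Optional descriptor name carried into the result.
#' @return A list of class `difference_test`: `descriptor`, `chosen_test`
#'   ("mann_whitney_u", "t_test" or "welch_t"), `statistic`, `p_value`,
#'   `direction`, `significant`, `alpha`, plus the gate p-values
#'   (`shapiro_p`, `levene_p`).
#' @export
difference_test <- function(x, y, alpha = 0.05, descriptor = NA_character_) {
  x <- x[is.finite(x)]; y <- y[is.finite(y)]
  if (length(x) < 3 || length(y) < 3) stop2("each sample needs at least 3 values")
  stopifnot(alpha >= 0, alpha <= 1)
  sw <- function(v) {
    if (stats::sd(v) == 0) return(NA_real_)  # constant sample: SW inapplicable
    if (length(v) > 5000) v <- v[seq(1, length(v), length.out = 5000)]
    stats::shapiro.test(v)$p.value
  }
  swx <- sw(x); swy <- sw(y)
  levene_p <- NA_real_
  if ((is.na(swx) || swx < alpha) || (is.na(swy) || swy < alpha)) {
    if (is.na(swx) || is.na(swy)) {
      warn2("constant sample: Shapiro-Wilk inapplicable, using Mann-Whitney U")
    }
    ht <- suppressWarnings(stats::wilcox.test(x, y, exact = FALSE))
    chosen <- "mann_whitney_u"
  } else {
    grp <- factor(rep(c("x", "y"), c(length(x), length(y))))
    lev <- car::leveneTest(c(x, y), grp, center = stats::median)
    levene_p <- lev[["Pr(>F)"]][1]
    if (levene_p < alpha) {
      ht <- stats::t.test(x, y, var.equal = FALSE)
      chosen <- "welch_t"
    } else {
      ht <- stats::t.test(x, y, var.equal = TRUE)
      chosen <- "t_test"
    }
  }
  structure(list(descriptor = descriptor, chosen_test = chosen,
                 statistic = unname(ht$statistic), p_value = ht$p.value,
                 direction = sign(stats::median(x) - stats::median(y)),
                 significant = ht$p.value < alpha, alpha = alpha,
                 shapiro_p = c(x = swx, y = swy), levene_p = levene_p),
            class = "difference_test")
}

#' Per-descriptor difference analysis between the two classes
#'
#' Runs [difference_test()] for every requested descriptor, green values
#' against non-green values. Missing descriptors are listed and skipped.
#'
#' @param green_desc,nongreen_desc Data frames of descriptors (rows =
#'   molecules) for the two classes, e.g. from [compute_descriptors()].
#' @param descriptors Descriptor names to test (default: the nine
#'   screening descriptors).
#' @param alpha Significance level (default 0.05).
#' @return A data.frame of class `difference_analysis`: descriptor,
#'   chosen_test, statistic, p_value, direction, significant; attribute
#'   `skipped` lists descriptors absent from either table.
#' @export
run_difference_analysis <- function(green_desc, nongreen_desc,
                                    descriptors = .MANDATORY_DESCRIPTORS,
                                    alpha = 0.05) {
  present <- descriptors[descriptors %in% names(green_desc) &
                           descriptors %in% names(nongreen_desc)]
  skipped <- setdiff(descriptors, present)
  if (length(skipped)) {
    warn2("descriptor(s) missing from input, skipped: %s",
          paste(skipped, collapse = ", "))
  }
  rows <- lapply(present, function(d) {
    r <- difference_test(green_desc[[d]], nongreen_desc[[d]], alpha = alpha,
                         descriptor = d)
    data.frame(descriptor = d, chosen_test = r$chosen_test,
               statistic = r$statistic, p_value = r$p_value,
               direction = r$direction, significant = r$significant,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "skipped") <- skipped
  attr(out, "alpha") <- alpha
  class(out) <- c("difference_analysis", "data.frame")
  out
}

#' Export factor-analysis and difference-analysis tables
#'
#' Writes the scree table (factor, eigenvalue), the loading matrix, the
#' screening list and the difference-analysis long table as CSV files.
#'
#' @param fr A `factor_result`.
#' @param da A `difference_analysis` (optional).
#' @param dir Output directory.
#' @param loading_threshold Screening threshold (default 0.75).
#' @return Invisibly, the paths written.
#' @export
write_descstats <- function(fr, da = NULL, dir = ".", loading_threshold = 0.75) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  scree <- data.frame(factor = seq_along(fr$eigenvalues),
                      eigenvalue = sprintf("%.6f", fr$eigenvalues))
  p <- file.path(dir, "scree.csv")
  utils::write.csv(scree, p, row.names = FALSE, quote = FALSE); paths <- c(paths, p)
  ld <- data.frame(descriptor = rownames(fr$loadings),
                   apply(fr$loadings, 2, function(v) sprintf("%.6f", v)))
  p <- file.path(dir, "loadings.csv")
  utils::write.csv(ld, p, row.names = FALSE, quote = FALSE); paths <- c(paths, p)
  p <- file.path(dir, "screened_descriptors.txt")
  writeLines(screen_descriptors(fr, loading_threshold), p); paths <- c(paths, p)
  if (!is.null(da)) {
    out <- da
    out$statistic <- sprintf("%.6f", out$statistic)
    out$p_value <- sprintf("%.6g", out$p_value)
    p <- file.path(dir, "difference_analysis.csv")
    utils::write.csv(out, p, row.names = FALSE, quote = FALSE); paths <- c(paths, p)
  }
  invisible(paths)
}
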