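test_that("KMO behaves as expected for correlated and independent batteries", {
  set.seed(30)
  f <- stats::rnorm(200)
  Xc <- cbind(a = f + stats::rnorm(200, sd = 0.45),
              b = f + stats::rnorm(200, sd = 0.45),
              c = f + stats::rnorm(200, sd = 0.45))
  expect_gt(kmo(Xc), 0.7)
  Xi <- matrix(stats::rnorm(500 * 5), 500, 5)
  expect_lt(abs(kmo(Xi) - 0.5), 0.12)
  expect_error(kmo(cbind(Xi, Xi[, 1])), "singular")
  expect_error(kmo(Xi[, 1:2]), "at least 3")
})

test_that("KMO matches a regression-based partial-correlation oracle", {
  set.seed(31)
  n <- 120; p <- 5
  f <- stats::rnorm(n)
  X <- vapply(1:p, function(j) 0.6 * f + stats::rnorm(n), numeric(n))
  colnames(X) <- paste0("v", 1:p)
  R <- stats::cor(X)
  # oracle: partial correlation of (i, j) given the rest via residuals of
  # two linear regressions
  Q <- matrix(0, p, p)
  for (i in 1:(p - 1)) for (j in (i + 1):p) {
    rest <- X[, -c(i, j), drop = FALSE]
    ri <- stats::resid(stats::lm(X[, i] ~ rest))
    rj <- stats::resid(stats::lm(X[, j] ~ rest))
    Q[i, j] <- stats::cor(ri, rj)
  }
  off <- upper.tri(R)
  kmo_oracle <- sum(R[off]^2) / (sum(R[off]^2) + sum(Q[off]^2))
  expect_equal(kmo(X), kmo_oracle, tolerance = 1e-6)
})

test_that("Bartlett's sphericity is null on orthogonal scores and rejects correlation", {
  set.seed(32)
  # principal-component scores are exactly uncorrelated: det R = 1
  pc <- stats::prcomp(matrix(stats::rnorm(300 * 4), 300, 4))$x
  bt <- bartlett_sphericity(pc)
  expect_lt(bt$chi2, 1e-6)
  expect_gt(bt$p_value, 0.999)
  expect_equal(bt$df, 4 * 3 / 2)
  f <- stats::rnorm(200)
  Xc <- cbind(f + stats::rnorm(200, sd = 0.3), f + stats::rnorm(200, sd = 0.3),
              stats::rnorm(200))
  expect_lt(bartlett_sphericity(Xc)$p_value, 0.001)
})

test_that("factor analysis recovers a planted two-factor structure", {
  set.seed(33)
  n <- 1000
  lam <- c(0.95, 0.9, 0.85, 0.9, 0.92, 0.88)
  F2 <- matrix(stats::rnorm(n * 2), n, 2)
  L <- rbind(cbind(lam[1:3], 0), cbind(0, lam[4:6]))
  X <- F2 %*% t(L) + matrix(stats::rnorm(n * 6, sd = 0.1), n, 6)
  colnames(X) <- paste0("v", 1:6)
  fr <- factor_analyze(X, n_factors = 2)
  # eigenvalue structure: two dominant factors
  expect_gt(fr$eigenvalues[2], 1)
  expect_lt(fr$eigenvalues[3], 0.5)
  expect_equal(sum(fr$eigenvalues), 6, tolerance = 1e-8)
  # recovered loadings match the standardized generating loadings up to
  # column order and sign
  truth <- lam / sqrt(lam^2 + 0.1^2)
  block <- rep(1:2, each = 3)
  got <- abs(fr$loadings)
  # match columns by where each block loads most heavily
  col_of_block1 <- which.max(colSums(got[1:3, ]))
  col_map <- c(col_of_block1, setdiff(1:2, col_of_block1))
  for (v in 1:6) {
    expect_lt(abs(got[v, col_map[block[v]]] - truth[v]), 0.1)
    expect_lt(got[v, col_map[3 - block[v]]], 0.25)  # cross-loadings near zero
  }
})

test_that("varimax rotation preserves communalities and the gates are enforced", {
  set.seed(34)
  f <- stats::rnorm(400)
  X <- vapply(1:5, function(j) 0.8 * f + stats::rnorm(400, sd = 0.6), numeric(400))
  colnames(X) <- paste0("v", 1:5)
  fr <- factor_analyze(X, n_factors = 2)
  R <- stats::cor(X)
  eg <- eigen(R, symmetric = TRUE)
  unrot <- eg$vectors[, 1:2] %*% diag(sqrt(eg$values[1:2]))
  expect_equal(unname(fr$communalities), rowSums(unrot^2), tolerance = 1e-8)
  expect_true(all(abs(fr$loadings) <= 1 + 1e-6))
  # each factor's largest-magnitude loading is positive
  for (j in 1:2) expect_gt(fr$loadings[which.max(abs(fr$loadings[, j])), j], 0)
  expect_error(factor_analyze(X, n_factors = 9), "exceeds")
  # independent noise fails the gates
  Xnull <- matrix(stats::rnorm(200 * 4), 200, 4)
  expect_error(factor_analyze(Xnull, n_factors = 2), "gates")
  expect_warning(factor_analyze(Xnull, n_factors = 2, enforce_gates = FALSE),
                 "gates")
})

test_that("single-variable factor analysis is the identity loading", {
  X <- matrix(stats::rnorm(50), dimnames = list(NULL, "only"))
  fr <- factor_analyze(X, n_factors = 1)
  expect_equal(unname(fr$loadings[1, 1]), 1)
})

test_that("screening retains descriptors strictly above the loading threshold", {
  # worked example: a published nine-descriptor component matrix
  tab <- utils::read.csv(system.file("extdata", "component_matrix_9x3.csv",
                                     package = "greenodor"), row.names = 1)
  kept <- screen_descriptors(as.matrix(tab), 0.75)
  expect_setequal(kept, rownames(tab))   # all nine descriptors pass
  expect_length(kept, 9)
  # strictness and degenerate cases
  m <- matrix(c(0.75, 0.76, 0.2, 0.1), 2, 2,
              dimnames = list(c("at", "above"), NULL))
  expect_equal(screen_descriptors(m, 0.75), "above")
  zeros <- matrix(0, 3, 2, dimnames = list(letters[1:3], NULL))
  expect_length(screen_descriptors(zeros), 0)
})

test_that("the difference-test decision tree routes by normality and variance", {
  set.seed(35)
  # identical samples: no significance
  x <- stats::rnorm(50)
  r0 <- difference_test(x, x)
  expect_false(r0$significant)
  expect_gt(r0$p_value, 0.9)
  # clear normal shift: a t-branch test with overwhelming significance
  r1 <- difference_test(stats::rnorm(100), stats::rnorm(100, mean = 2))
  expect_true(r1$chosen_test %in% c("t_test", "welch_t"))
  expect_lt(r1$p_value, 1e-10)
  expect_equal(r1$direction, -1)
  # exponential data: Shapiro-Wilk rejects, Mann-Whitney takes over
  r2 <- difference_test(stats::rexp(100), stats::rexp(100) + 0.5)
  expect_equal(r2$chosen_test, "mann_whitney_u")
  # unequal variances with normal data: Welch branch
  r3 <- difference_test(stats::rnorm(150, sd = 1), stats::rnorm(150, sd = 4))
  expect_equal(r3$chosen_test, "welch_t")
  # constant sample routes to Mann-Whitney with a warning
  expect_warning(r4 <- difference_test(rep(1, 10), stats::rnorm(10)),
                 "constant")
  expect_equal(r4$chosen_test, "mann_whitney_u")
  expect_error(difference_test(1:2, stats::rnorm(5)), "at least 3")
})

test_that("difference tests are symmetric under sample swap", {
  set.seed(36)
  for (gen in list(function() stats::rnorm(40), function() stats::rexp(40))) {
    x <- gen(); y <- gen() + 0.5
    a <- suppressWarnings(difference_test(x, y))
    b <- suppressWarnings(difference_test(y, x))
    expect_equal(a$p_value, b$p_value, tolerance = 1e-9)
    expect_equal(a$chosen_test, b$chosen_test)
    expect_equal(a$direction, -b$direction)
  }
})

test_that("difference analysis recovers the planted class contrasts", {
  fx <- fixture_synth200()
  green <- fx$desc[fx$green, ]
  nongreen <- fx$desc[!fx$green, ]
  da <- run_difference_analysis(green, nongreen, alpha = 0.05)
  expect_equal(nrow(da), 9)
  molwt <- da[da$descriptor == "MolWt", ]
  tpsa <- da[da$descriptor == "TPSA", ]
  expect_true(molwt$significant && molwt$direction == -1)
  expect_true(tpsa$significant && tpsa$direction == -1)
  # the size/electron-count/surface descriptors all run lower in green
  for (d in c("NumValenceElectrons", "PSA", "HeavyAtomMolWt")) {
    expect_equal(da$direction[da$descriptor == d], -1)
  }
  # alpha = 0 switches everything off
  da0 <- run_difference_analysis(green, nongreen, alpha = 0)
  expect_false(any(da0$significant))
  # missing descriptors are skipped with a warning
  expect_warning(
    da_m <- run_difference_analysis(green[, 1:3], nongreen,
                                    descriptors = c(names(green)[1:3], "Ghost")),
    "Ghost")
  expect_equal(attr(da_m, "skipped"), "Ghost")
})

test_that("label shuffling yields a false-positive fraction near alpha", {
  fx <- fixture_synth200()
  vals <- fx$desc[stats::complete.cases(fx$desc), 1:9]
  n <- nrow(vals)
  set.seed(37)
  hits <- 0; total <- 0
  for (s in 1:60) {
    idx <- sample(n)
    g <- vals[idx[1:(n %/% 2)], ]
    ng <- vals[idx[(n %/% 2 + 1):n], ]
    da <- suppressWarnings(run_difference_analysis(g, ng, alpha = 0.05))
    hits <- hits + sum(da$significant)
    total <- total + nrow(da)
  }
  expect_gt(hits / total, 0.005)
  expect_lt(hits / total, 0.12)
})

test_that("descstats CSV export writes scree, loadings, screening and differences", {
  fx <- fixture_synth200()
  keep <- stats::complete.cases(fx$desc)
  X <- fx$desc[keep, c("MolWt", "HeavyAtomMolWt", "NumValenceElectrons",
                       "TPSA", "FpDensityMorgan1", "FpDensityMorgan2")]
  fr <- suppressWarnings(factor_analyze(X, n_factors = 2, enforce_gates = FALSE))
  da <- run_difference_analysis(fx$desc[fx$green, ], fx$desc[!fx$green, ])
  dir <- withr::local_tempdir()
  paths <- write_descstats(fr, da, dir)
  expect_true(all(file.exists(paths)))
  scree <- utils::read.csv(paths[1])
  expect_equal(nrow(scree), 6)
})
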