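# Exact (quadratic) t-distributed Stochastic Neighbor Embedding.
# Molecule sets in this package are a few hundred points, so the O(n^2)
# formulation with vectorized gradient updates is fast and keeps the
# embedding fully deterministic under a seed.

# per-point precision (beta = 1/(2 sigma^2)) calibrated by bisection so the
# conditional distribution has the requested perplexity
.tsne_cond_p <- function(D2, perplexity, tol = 1e-5) {
  n <- nrow(D2)
  P <- matrix(0, n, n)
  logU <- log(perplexity)
  for (i in seq_len(n)) {
    di <- D2[i, -i]
    if (all(di == 0)) {            # coincident points: uniform affinities
      P[i, -i] <- 1 / (n - 1)
      next
    }
    beta <- 1; bmin <- -Inf; bmax <- Inf
    for (iter in 1:50) {
      w <- exp(-di * beta)
      sw <- sum(w)
      if (sw == 0) { H <- 0; p <- w }
      else {
        p <- w / sw
        H <- -sum(p[p > 0] * log(p[p > 0]))
      }
      diff <- H - logU
      if (abs(diff) < tol) break
      if (diff > 0) { bmin <- beta; beta <- if (is.finite(bmax)) (beta + bmax) / 2 else beta * 2 }
      else { bmax <- beta; beta <- if (is.finite(bmin)) (beta + bmin) / 2 else beta / 2 }
    }
    P[i, -i] <- p
  }
  P
}

# D2: squared distance matrix; returns n x 2 coordinates
.tsne_embed <- function(D2, perplexity = 30, seed = 1, max_iter = 500,
                        eta = 200, exaggeration = 12, exaggerate_iter = 100) {
  n <- nrow(D2)
  P <- .tsne_cond_p(D2, perplexity)
  P <- (P + t(P)) / (2 * n)
  P <- pmax(P, 1e-12)
  with_local_seed(seed, {
    Y <- matrix(stats::rnorm(n * 2, sd = 1e-4), n, 2)
    V <- matrix(0, n, 2)
    gains <- matrix(1, n, 2)
    Pex <- P * exaggeration
    for (it in seq_len(max_iter)) {
      Puse <- if (it <= exaggerate_iter) Pex else P
      sumY <- rowSums(Y^2)
      num <- 1 / (1 + outer(sumY, sumY, "+") - 2 * tcrossprod(Y))
      diag(num) <- 0
      Q <- pmax(num / sum(num), 1e-12)
      W <- (Puse - Q) * num
      grad <- 4 * (diag(rowSums(W)) %*% Y - W %*% Y)
      mom <- if (it <= 250) 0.5 else 0.8
      gains <- ifelse(sign(grad) != sign(V), gains + 0.2, gains * 0.8)
      gains[gains < 0.01] <- 0.01
      V <- mom * V - eta * gains * grad
      Y <- Y + V
      Y <- sweep(Y, 2, colMeans(Y))
      if (!all(is.finite(Y))) {
        stop2("t-SNE diverged to non-finite coordinates at iteration %d", it)
      }
    }
    Y
  })
}
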