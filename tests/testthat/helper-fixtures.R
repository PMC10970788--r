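# Shared fixtures (memoized: built once per test run) and independent
# brute-force oracles used across the suite.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_env)) {
    assign(name, builder(), envir = .fixture_env)
  }
  get(name, envir = .fixture_env)
}

# 200 + 200 synthetic molecules with their descriptor battery
fixture_synth200 <- function() {
  fixture("synth200", function() {
    ds <- generate_synthetic(200, 200, seed = 101, report = FALSE)
    desc <- compute_descriptors(stats::setNames(ds$smiles_canonical, ds$name))
    list(ds = ds, desc = desc, green = ds$label == "green")
  })
}

# small cleaned synthetic dataset for pipeline-level tests
fixture_synth_small <- function() {
  fixture("synth_small", function() {
    generate_synthetic(40, 40, seed = 202, report = FALSE)
  })
}

# ---- independent oracles -------------------------------------------------

# O(n^2) union-find connected components of the strict proximity graph
oracle_union_find_clusters <- function(coords, cutoff) {
  n <- nrow(coords)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (sqrt(sum((coords[i, ] - coords[j, ])^2)) < cutoff) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[ri] <- rj
      }
    }
  }
  roots <- vapply(seq_len(n), find, 1L)
  match(roots, unique(roots))
}

# exhaustive pair-counting AUC
oracle_auc <- function(y_true, scores) {
  pos <- which(y_true == "green"); neg <- which(y_true == "nongreen")
  tot <- 0
  for (i in pos) for (j in neg) {
    tot <- tot + if (scores[i] > scores[j]) 1 else if (scores[i] == scores[j]) 0.5 else 0
  }
  tot / (length(pos) * length(neg))
}

# precision-at-rank summation AP
oracle_ap <- function(y_true, scores) {
  ord <- order(scores, decreasing = TRUE)
  lab <- y_true[ord] == "green"
  hits <- 0; s <- 0
  for (k in seq_along(lab)) {
    if (lab[k]) { hits <- hits + 1; s <- s + hits / k }
  }
  s / sum(lab)
}

# Floyd-Warshall all-pairs shortest paths on an unweighted edge list
oracle_fw_dist <- function(n, edges) {
  d <- matrix(Inf, n, n); diag(d) <- 0
  for (r in seq_len(nrow(edges))) {
    d[edges[r, 1], edges[r, 2]] <- 1
    d[edges[r, 2], edges[r, 1]] <- 1
  }
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n)) {
    if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
  }
  d
}

# build a fingerprint-like 0/1 matrix with the given on-bit sets
bits_from_sets <- function(sets, nbits) {
  t(vapply(sets, function(s) { b <- integer(nbits); b[s] <- 1L; b },
           integer(nbits)))
}

# relabel cluster vectors canonically (by first appearance) for comparison
canon_labels <- function(lab) match(lab, unique(lab))
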