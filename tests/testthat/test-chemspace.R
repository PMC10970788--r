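test_that("2-D embedding is deterministic, finite, and separates planted groups", {
  set.seed(20)
  X <- rbind(bits_from_sets(replicate(12, sample(1:60, 15), simplify = FALSE), 200),
             bits_from_sets(replicate(12, sample(71:130, 15), simplify = FALSE), 200),
             bits_from_sets(replicate(12, sample(141:200, 15), simplify = FALSE), 200))
  e1 <- embed_2d(X, seed = 3, perplexity = 8)
  e2 <- embed_2d(X, seed = 3, perplexity = 8)
  expect_identical(e1$coords, e2$coords)
  expect_true(all(is.finite(e1$coords)))
  grp <- rep(1:3, each = 12)
  D <- as.matrix(stats::dist(e1$coords))
  within <- mean(D[grp == 1, grp == 1])
  between <- mean(D[grp == 1, grp == 2])
  expect_lt(within, between)
  # degenerate input: identical fingerprints must still embed finitely
  Xdup <- bits_from_sets(rep(list(c(2, 9, 17)), 10), 64)
  ed <- embed_2d(Xdup, seed = 1, perplexity = 3)
  expect_true(all(is.finite(ed$coords)))
  expect_error(embed_2d(X[1:2, ], seed = 1), "at least 3")
  expect_error(embed_2d(X, seed = 1, perplexity = 50), "perplexity")
  # the pluggable alternative embedding obeys the same contract
  em <- embed_2d(X, seed = 1, method = "mds")
  expect_equal(dim(em$coords), c(36, 2))
  expect_true(all(is.finite(em$coords)))
})

test_that("the cutoff rule forces two points into singletons and chains close points", {
  # two points: cutoff = d/24 < d
  cl2 <- threshold_cluster(rbind(c(0, 0), c(1, 0)))
  expect_equal(sort(cl2$labels), 1:2)
  expect_equal(cl2$cutoff, 1 / 24)
  # collinear chain spaced exactly at the cutoff: strict inequality keeps
  # every point a singleton
  chain <- cbind(seq(0, 24, by = 1), 0)
  cl_eq <- threshold_cluster(chain)
  expect_equal(length(unique(cl_eq$labels)), 25)
  # compress the chain below the cutoff and append a far point: the chain
  # fuses into one cluster of 25
  chain09 <- cbind(seq(0, by = 0.9, length.out = 25), 0)
  far <- rbind(chain09, c(24, 0))
  cl_chain <- threshold_cluster(far)
  expect_equal(max(table(cl_chain$labels)), 25)
  expect_equal(length(unique(cl_chain$labels)), 2)
})

test_that("clustering equals union-find and single-linkage oracles on random instances", {
  set.seed(21)
  for (i in 1:5) {
    pts <- matrix(stats::runif(200 * 2, 0, 10), 200, 2)
    cl <- threshold_cluster(pts)
    expect_equal(canon_labels(cl$labels),
                 canon_labels(oracle_union_find_clusters(pts, cl$cutoff)))
    hc <- stats::hclust(stats::dist(pts), method = "single")
    expect_equal(canon_labels(cl$labels),
                 canon_labels(stats::cutree(hc, h = cl$cutoff)))
  }
})

test_that("clustering is invariant to reordering and uniform scaling", {
  set.seed(22)
  pts <- matrix(stats::rnorm(80 * 2), 80, 2)
  cl <- threshold_cluster(pts)
  expect_equal(sum(table(cl$labels)), 80)
  perm <- sample(80)
  cl_p <- threshold_cluster(pts[perm, ])
  expect_equal(canon_labels(cl$labels[perm]), canon_labels(cl_p$labels))
  cl_s <- threshold_cluster(pts * 37.5)
  expect_equal(cl$labels, cl_s$labels)
  expect_equal(cl_s$cutoff, cl$cutoff * 37.5)
  # coincident points degenerate to one cluster with a warning
  expect_warning(cl_d <- threshold_cluster(matrix(1, 5, 2)), "coincide")
  expect_equal(cl_d$labels, rep(1L, 5))
})

test_that("major-cluster filtering keeps clusters at the size threshold", {
  labels <- rep(1:3, c(40, 35, 29))
  f <- filter_major_clusters(labels, 30)
  expect_setequal(f$retained, 1:2)
  expect_equal(f$n_molecules, 75)
  singles <- seq_len(10)
  f2 <- filter_major_clusters(singles, 30)
  expect_length(f2$retained, 0)
  expect_equal(f2$n_molecules, 0)
})

test_that("the CSN edge set matches a brute-force pair scan with Dice weights", {
  set.seed(23)
  n <- 100
  pts <- matrix(stats::runif(n * 2, 0, 5), n, 2)
  fp <- bits_from_sets(replicate(n, sample(1:96, 12), simplify = FALSE), 96)
  cl <- threshold_cluster(pts)
  net <- build_csn(pts, fp, cl, cl$cutoff)
  got <- igraph::as_edgelist(net, names = FALSE)
  got <- got[order(got[, 1], got[, 2]), , drop = FALSE]
  want <- list(); wdice <- c()
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    if (sqrt(sum((pts[i, ] - pts[j, ])^2)) < cl$cutoff) {
      want[[length(want) + 1]] <- c(i, j)
      wdice <- c(wdice, dice_similarity(fp[i, ], fp[j, ]))
    }
  }
  want <- do.call(rbind, want)
  expect_equal(got, want)
  expect_true(all(igraph::E(net)$dice >= 0 & igraph::E(net)$dice <= 1))
  # network components coincide with cluster labels
  comp <- igraph::components(net)$membership
  expect_equal(canon_labels(as.integer(comp)), canon_labels(cl$labels))
  # two singleton clusters yield no edges
  net0 <- build_csn(rbind(c(0, 0), c(9, 9)), fp[1:2, ], c(1, 2), 0.1)
  expect_equal(igraph::ecount(net0), 0)
})

test_that("representatives maximize closeness centrality (star, path, random oracle)", {
  mk_csn <- function(n, edges, cluster = rep(1, n)) {
    g <- igraph::make_empty_graph(n, directed = FALSE)
    if (nrow(edges)) g <- igraph::add_edges(g, t(edges))
    igraph::V(g)$name <- paste0("m", seq_len(n))
    igraph::V(g)$cluster <- cluster
    class(g) <- c("csn", class(g))
    g
  }
  # star: the hub has closeness exactly 1
  star <- mk_csn(5, cbind(1, 2:5))
  r <- representative_molecule(star, 1)
  expect_equal(r$name, "m1")
  expect_equal(r$score, 1)
  # path a-b-c: the middle node wins
  path <- mk_csn(3, rbind(c(1, 2), c(2, 3)))
  expect_equal(representative_molecule(path, 1)$name, "m2")
  # random 20-node graph against a Floyd-Warshall oracle
  set.seed(24)
  edges <- which(upper.tri(matrix(0, 20, 20)) &
                   matrix(stats::runif(400) < 0.15, 20, 20), arr.ind = TRUE)
  net <- mk_csn(20, edges)
  d <- oracle_fw_dist(20, edges)
  wf <- vapply(1:20, function(v) {
    di <- d[v, -v]; reach <- di[is.finite(di)]
    if (!length(reach) || sum(reach) == 0) return(0)
    (length(reach) / 19) * (length(reach) / sum(reach))
  }, 0)
  r20 <- representative_molecule(net, 1)
  expect_equal(r20$name, paste0("m", which.max(wf)))
  expect_equal(r20$score, max(wf), tolerance = 1e-12)
  # singleton cluster is its own representative with score 0
  lone <- mk_csn(3, rbind(c(1, 2)), cluster = c(1, 1, 2))
  r1 <- representative_molecule(lone, 2)
  expect_equal(r1$name, "m3")
  expect_equal(r1$score, 0)
})

test_that("the mean-Dice representative rule agrees with direct averaging", {
  set.seed(25)
  n <- 12
  fp <- bits_from_sets(replicate(n, sample(1:64, 10), simplify = FALSE), 64)
  g <- igraph::make_full_graph(n)
  igraph::V(g)$name <- paste0("m", 1:n)
  igraph::V(g)$cluster <- 1
  class(g) <- c("csn", class(g))
  r <- representative_molecule(g, 1, rule = "mean_dice", fingerprints = fp)
  S <- dice_matrix(fp)
  means <- (rowSums(S) - 1) / (n - 1)
  expect_equal(r$name, paste0("m", which.max(means)))
})

test_that("CSN exports round-trip through the CSV dialect and GraphML", {
  set.seed(26)
  pts <- matrix(stats::runif(20), 10, 2)
  fp <- bits_from_sets(replicate(10, sample(1:32, 6), simplify = FALSE), 32)
  cl <- threshold_cluster(pts, cutoff_divisor = 3)
  net <- build_csn(pts, fp, cl, cl$cutoff)
  prefix <- file.path(withr::local_tempdir(), "csn")
  write_csn(net, prefix, format = "csv")
  back <- read_csn_csv(prefix)
  expect_equal(igraph::vcount(back), 10)
  expect_equal(igraph::ecount(back), igraph::ecount(net))
  expect_equal(igraph::V(back)$cluster, igraph::V(net)$cluster)
  expect_equal(igraph::E(back)$dice, igraph::E(net)$dice, tolerance = 1e-9)
  gml <- file.path(withr::local_tempdir(), "net.graphml")
  write_csn(net, gml, format = "graphml")
  expect_true(file.size(gml) > 0)
})
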