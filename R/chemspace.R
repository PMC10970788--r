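# Chemical-space analysis of the positive class: 2-D embedding of the
# fingerprints, distance-cutoff clustering, the Dice-weighted chemical
# space network (CSN) and representative-molecule selection.

#' Embed fingerprints in two dimensions
#'
#' Default method is t-SNE on the Euclidean fingerprint distances,
#' implemented in-package and deterministic given the seed. `"mds"`
#' (classical metric scaling via [stats::cmdscale()]) is available as a
#' faster deterministic alternative; any method satisfying
#' determinism-under-seed can stand behind this contract.
#'
#' @param fingerprints Molecules x bits 0/1 matrix (or the result of
#'   [morgan_fingerprints()]).
#' @param seed Integer seed.
#' @param perplexity t-SNE perplexity (default 30; must be < number of
#'   molecules).
#' @param method `"tsne"` (default) or `"mds"`.
#' @param max_iter t-SNE iteration budget.
#' @return A list of class `embedding2d`: `coords` (n x 2 matrix, finite),
#'   `method`, `perplexity`, `seed`.
#' @export
embed_2d <- function(fingerprints, seed = 1, perplexity = 30,
                     method = c("tsne", "mds"), max_iter = 500) {
  method <- match.arg(method)
  m <- if (is.list(fingerprints)) fingerprints$matrix else fingerprints
  m <- as.matrix(m)
  n <- nrow(m)
  if (n < 3) stop2("need at least 3 molecules to embed (got %d)", n)
  if (method == "tsne" && perplexity >= n) {
    stop2("perplexity (%g) must be smaller than the number of molecules (%d); try perplexity = %d",
          perplexity, n, max(2L, floor((n - 1) / 3)))
  }
  storage.mode(m) <- "double"
  s <- rowSums(m^2)
  D2 <- pmax(outer(s, s, "+") - 2 * tcrossprod(m), 0)
  coords <- if (method == "tsne") {
    .tsne_embed(D2, perplexity = perplexity, seed = seed, max_iter = max_iter)
  } else {
    d <- stats::as.dist(sqrt(D2))
    xy <- stats::cmdscale(d, k = 2)
    if (ncol(xy) < 2) xy <- cbind(xy, 0)[, 1:2, drop = FALSE]
    xy
  }
  rownames(coords) <- rownames(m)
  colnames(coords) <- c("x", "y")
  structure(list(coords = coords, method = method,
                 perplexity = perplexity, seed = seed),
            class = "embedding2d")
}

#' Distance-cutoff clustering in the embedded plane
#'
#' Two molecules belong to the same group when their Euclidean distance is
#' strictly less than `1/cutoff_divisor` of the distance between the two
#' furthest molecules; groups are the connected components of this
#' proximity graph (equivalently, single-linkage clusters cut at the
#' cutoff). Cluster ids are assigned by decreasing cluster size, ties by
#' first-member order. If all points coincide the cutoff is 0 and the rule
#' would make every point a singleton; that degenerate case returns a
#' single cluster with a warning.
#'
#' @param coords n x 2 coordinate matrix (or an `embedding2d`).
#' @param cutoff_divisor Divisor of the maximum pairwise distance
#'   (default 24).
#' @return A list of class `threshold_clustering`: `labels` (integer
#'   cluster ids), `cutoff`, `max_distance`, `sizes` (named table).
#' @export
threshold_cluster <- function(coords, cutoff_divisor = 24) {
  if (inherits(coords, "embedding2d")) coords <- coords$coords
  coords <- as.matrix(coords)
  n <- nrow(coords)
  if (n < 2) stop2("need at least 2 points to cluster")
  stopifnot(cutoff_divisor > 0)
  D <- as.matrix(stats::dist(coords))
  dmax <- max(D)
  cutoff <- dmax / cutoff_divisor
  if (dmax == 0) {
    warn2("all points coincide; returning a single cluster (cutoff 0)")
    labels <- rep(1L, n)
  } else {
    adj <- D < cutoff
    g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected",
                                             diag = FALSE)
    comp <- igraph::components(g)$membership
    labels <- .relabel_by_size(comp)
  }
  structure(list(labels = labels, cutoff = cutoff, max_distance = dmax,
                 sizes = table(labels)),
            class = "threshold_clustering")
}

# ids ordered by decreasing size, ties broken by first appearance
.relabel_by_size <- function(membership) {
  first <- tapply(seq_along(membership), membership, min)
  sizes <- tabulate(membership)
  ord <- order(-sizes[as.integer(names(first))], first)
  new_id <- integer(length(first))
  new_id[as.integer(names(first))[ord]] <- seq_along(ord)
  new_id[membership]
}

#' Retain major clusters
#'
#' @param labels Integer cluster labels (or a `threshold_clustering`).
#' @param min_major_size Minimum size for a cluster to be retained
#'   (default 30).
#' @return A list: `retained` (cluster ids), `n_molecules` (total count in
#'   retained clusters), `sizes` (sizes of retained clusters).
#' @export
filter_major_clusters <- function(labels, min_major_size = 30) {
  if (inherits(labels, "threshold_clustering")) labels <- labels$labels
  sizes <- table(labels)
  keep <- sizes[sizes >= min_major_size]
  list(retained = as.integer(names(keep)),
       n_molecules = sum(keep),
       sizes = as.integer(keep))
}

#' Build the chemical space network
#'
#' Nodes are molecules placed at their embedded coordinates with their
#' cluster id; edges connect every pair closer than the cutoff and carry
#' the Dice similarity of the two fingerprints as weight. Connected
#' components of the network coincide with the cluster labels by
#' construction.
#'
#' @param embedding An `embedding2d` (or n x 2 coordinate matrix).
#' @param fingerprints Molecules x bits 0/1 matrix.
#' @param labels Cluster labels (or a `threshold_clustering`).
#' @param cutoff Edge distance cutoff (typically from
#'   [threshold_cluster()]).
#' @param names Optional molecule names (default from row names).
#' @return An `igraph` graph of class `csn` with vertex attributes `name`,
#'   `x`, `y`, `cluster` and edge attributes `distance`, `dice`.
#' @export
build_csn <- function(embedding, fingerprints, labels, cutoff, names = NULL) {
  coords <- if (inherits(embedding, "embedding2d")) embedding$coords else as.matrix(embedding)
  if (inherits(labels, "threshold_clustering")) labels <- labels$labels
  m <- if (is.list(fingerprints)) fingerprints$matrix else fingerprints
  m <- as.matrix(m)
  n <- nrow(coords)
  stopifnot(nrow(m) == n, length(labels) == n)
  nm <- names %||% rownames(coords) %||% paste0("mol", seq_len(n))
  D <- as.matrix(stats::dist(coords))
  S <- dice_matrix(m)
  pairs <- which(upper.tri(D) & D < cutoff, arr.ind = TRUE)
  g <- igraph::make_empty_graph(n, directed = FALSE)
  igraph::V(g)$name <- nm
  igraph::V(g)$x <- coords[, 1]
  igraph::V(g)$y <- coords[, 2]
  igraph::V(g)$cluster <- labels
  if (nrow(pairs)) {
    g <- igraph::add_edges(g, t(pairs))
    igraph::E(g)$distance <- D[pairs]
    igraph::E(g)$dice <- S[pairs]
  }
  g <- igraph::set_graph_attr(g, "cutoff", cutoff)
  class(g) <- c("csn", class(g))
  g
}

#' Representative molecule of a cluster
#'
#' The primary rule picks the member maximising closeness centrality on the
#' cluster's (unweighted) CSN subgraph, using the Wasserman-Faust
#' composite `C(v) = (r_v/(n-1)) * (r_v / sum of distances to reachable
#' nodes)` with `r_v` the number of nodes reachable from `v`, which handles
#' disconnected subgraphs gracefully. The alternative rule picks the
#' member with the highest mean Dice similarity to all other members. Ties
#' break by input order; a singleton cluster is its own representative
#' with centrality 0.
#'
#' @param network A `csn` graph from [build_csn()].
#' @param cluster_id Cluster id to summarise.
#' @param rule `"closeness"` (default) or `"mean_dice"`.
#' @param fingerprints Required for `rule = "mean_dice"`: the fingerprint
#'   matrix used to build the network.
#' @return A list: `name`, `index` (vertex index in the network), `score`,
#'   `rule`.
#' @export
representative_molecule <- function(network, cluster_id,
                                    rule = c("closeness", "mean_dice"),
                                    fingerprints = NULL) {
  rule <- match.arg(rule)
  members <- which(igraph::V(network)$cluster == cluster_id)
  if (!length(members)) stop2("cluster %s has no members", cluster_id)
  if (length(members) == 1) {
    return(list(name = igraph::V(network)$name[members], index = members,
                score = 0, rule = rule))
  }
  if (rule == "closeness") {
    sub <- igraph::induced_subgraph(network, members)
    d <- igraph::distances(sub, weights = NA)
    score <- vapply(seq_along(members), function(i) {
      di <- d[i, -i]
      reach <- di[is.finite(di)]
      r <- length(reach)
      if (r == 0 || sum(reach) == 0) return(0)
      (r / (length(members) - 1)) * (r / sum(reach))
    }, 0)
  } else {
    if (is.null(fingerprints)) stop2("rule 'mean_dice' needs the fingerprint matrix")
    m <- if (is.list(fingerprints)) fingerprints$matrix else fingerprints
    S <- dice_matrix(m[members, , drop = FALSE])
    score <- (rowSums(S) - diag(S)) / (length(members) - 1)
  }
  best <- which.max(score)
  list(name = igraph::V(network)$name[members[best]],
       index = members[best], score = score[best], rule = rule)
}

#' Summarise clusters with their representatives
#'
#' @param network A `csn` graph.
#' @param min_major_size Only clusters at least this large are summarised
#'   (default 1 = all).
#' @param rule Representative rule, see [representative_molecule()].
#' @param fingerprints Fingerprint matrix (needed for `rule="mean_dice"`).
#' @return A data.frame: cluster, size, representative, score.
#' @export
cluster_summary <- function(network, min_major_size = 1,
                            rule = "closeness", fingerprints = NULL) {
  cl <- igraph::V(network)$cluster
  sizes <- table(cl)
  keep <- as.integer(names(sizes)[sizes >= min_major_size])
  rows <- lapply(keep, function(k) {
    rep <- representative_molecule(network, k, rule = rule,
                                   fingerprints = fingerprints)
    data.frame(cluster = k, size = as.integer(sizes[as.character(k)]),
               representative = rep$name, score = rep$score)
  })
  do.call(rbind, rows)
}

#' Export / import a chemical space network
#'
#' `write_csn` writes either GraphML (single file) or the two-file CSV
#' dialect (`<prefix>_nodes.csv`: name,x,y,cluster and
#' `<prefix>_edges.csv`: source,target,dice,distance). `read_csn_csv`
#' rebuilds the graph from the CSV pair, round-tripping losslessly up to
#' numeric formatting.
#'
#' @param network A `csn` graph.
#' @param path GraphML file path, or prefix for the CSV pair.
#' @param format `"graphml"` or `"csv"`.
#' @return Invisibly, the path(s) written.
#' @export
write_csn <- function(network, path, format = c("graphml", "csv")) {
  format <- match.arg(format)
  if (format == "graphml") {
    g <- network
    class(g) <- setdiff(class(g), "csn")
    igraph::write_graph(g, path, format = "graphml")
    return(invisible(path))
  }
  nodes <- data.frame(name = igraph::V(network)$name,
                      x = sprintf("%.10g", igraph::V(network)$x),
                      y = sprintf("%.10g", igraph::V(network)$y),
                      cluster = igraph::V(network)$cluster)
  ends <- igraph::as_edgelist(network, names = FALSE)
  edges <- data.frame(source = if (nrow(ends)) ends[, 1] else integer(0),
                      target = if (nrow(ends)) ends[, 2] else integer(0),
                      dice = sprintf("%.10g", igraph::E(network)$dice %||% numeric(0)),
                      distance = sprintf("%.10g", igraph::E(network)$distance %||% numeric(0)))
  p1 <- paste0(path, "_nodes.csv"); p2 <- paste0(path, "_edges.csv")
  utils::write.csv(nodes, p1, row.names = FALSE, quote = TRUE)
  utils::write.csv(edges, p2, row.names = FALSE, quote = TRUE)
  invisible(c(p1, p2))
}

#' @rdname write_csn
#' @param prefix Prefix used when the pair was written.
#' @export
read_csn_csv <- function(prefix) {
  nodes <- utils::read.csv(paste0(prefix, "_nodes.csv"), stringsAsFactors = FALSE)
  edges <- utils::read.csv(paste0(prefix, "_edges.csv"), stringsAsFactors = FALSE)
  g <- igraph::make_empty_graph(nrow(nodes), directed = FALSE)
  igraph::V(g)$name <- nodes$name
  igraph::V(g)$x <- as.numeric(nodes$x)
  igraph::V(g)$y <- as.numeric(nodes$y)
  igraph::V(g)$cluster <- nodes$cluster
  if (nrow(edges)) {
    g <- igraph::add_edges(g, rbind(edges$source, edges$target))
    igraph::E(g)$dice <- as.numeric(edges$dice)
    igraph::E(g)$distance <- as.numeric(edges$distance)
  }
  class(g) <- c("csn", class(g))
  g
}
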