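#' Nearest-neighbour graph over neuron trajectories
#'
#' Builds an undirected, unweighted graph on the P neurons: each neuron is
#' linked to its \code{k} nearest neighbours by Hamming distance between
#' binary trajectories (equivalently Manhattan distance on \{0,1\} rows), and
#' the directed k-NN relations are symmetrized by union. Ties in distance are
#' broken deterministically in favour of the lower neuron index.
#'
#' Neighbour search is exact by default. At the scale this package targets
#' (hundreds of neurons) exact search costs the same as approximate kd-tree
#' search and keeps results deterministic; pass \code{approximate = TRUE} to
#' subsample candidate neighbours for very large P.
#'
#' @param E an \code{\link{event_matrix}} (or plain binary matrix), P >= 2.
#' @param k number of nearest neighbours per neuron, in \code{[1, P-1]}
#'   (default 10).
#' @param approximate logical; if TRUE, each neuron's neighbours are searched
#'   among a random candidate subset of size \code{max(10 k, 100)} (seeded by
#'   \code{seed}), trading exactness for speed.
#' @param seed RNG seed used only when \code{approximate = TRUE}.
#' @return An \code{igraph} undirected graph with P vertices named by neuron
#'   id and no self loops.
#' @examples
#' E <- event_matrix(matrix(rbinom(60, 1, 0.3), nrow = 6))
#' g <- build_neighbor_graph(E, k = 2)
#' igraph::vcount(g)
#' @export
build_neighbor_graph <- function(E, k = 10, approximate = FALSE, seed = NULL) {
  v <- as_event_values(E)
  if (nrow(v) < 2L) stop("need at least 2 neurons to build a neighbour graph")
  g <- knn_graph_from_dist(hamming_dist(v), k, approximate = approximate,
                           seed = seed)
  igraph::V(g)$name <- rownames(v)
  g
}

# k-NN graph from a precomputed distance matrix (union-symmetrized).
knn_graph_from_dist <- function(D, k, approximate = FALSE, seed = NULL) {
  P <- nrow(D)
  k <- as.integer(k)
  if (k < 1L || k > P - 1L)
    stop("k must lie in [1, P-1]; got k=", k, " with P=", P)
  cand_all <- seq_len(P)
  if (approximate && !is.null(seed)) set.seed(seed)
  n_cand <- max(10L * k, 100L)
  nbrs <- vector("list", P)
  for (i in seq_len(P)) {
    cand <- cand_all[-i]
    if (approximate && length(cand) > n_cand)
      cand <- sort(sample(cand, n_cand))
    # order() is stable, so equal distances resolve to the lower index
    nbrs[[i]] <- cand[order(D[i, cand])][seq_len(min(k, length(cand)))]
  }
  edges <- rbind(rep(seq_len(P), lengths(nbrs)), unlist(nbrs))
  g <- igraph::graph_from_edgelist(t(edges), directed = TRUE)
  g <- igraph::add_vertices(g, max(0L, P - igraph::vcount(g)))
  igraph::as_undirected(g, mode = "collapse")
}

# Pairwise Hamming distance between binary rows.
hamming_dist <- function(v) {
  as.matrix(stats::dist(v, method = "manhattan"))
}

#' Partition a neighbour graph by walktrap community detection
#'
#' Runs the walktrap algorithm (short random walks, bottom-up merging) and
#' cuts the resulting dendrogram at the maximum-modularity level, so the
#' number of clusters K is selected by the data, never by the user.
#' Disconnected graphs are handled per connected component; K is the total
#' community count. A graph with no edges yields the all-singletons partition
#' with a warning.
#'
#' @param g an undirected \code{igraph} graph as produced by
#'   \code{\link{build_neighbor_graph}}.
#' @param steps random-walk length (default 4, the algorithm's canonical
#'   default).
#' @return An integer vector of cluster labels in \code{1..K}, named by
#'   vertex, with attribute \code{"K"}.
#' @export
walktrap_partition <- function(g, steps = 4) {
  stopifnot(igraph::is_igraph(g))
  P <- as.integer(igraph::vcount(g))
  labels <- integer(P)
  names(labels) <- igraph::V(g)$name
  if (igraph::ecount(g) == 0L) {
    warning("graph has no edges; every neuron becomes its own cluster")
    labels[] <- seq_len(P)
    attr(labels, "K") <- P
    return(labels)
  }
  comp <- igraph::components(g)
  offset <- 0L
  for (cid in seq_len(comp$no)) {
    vs <- which(comp$membership == cid)
    if (length(vs) == 1L) {
      labels[vs] <- offset + 1L
      offset <- offset + 1L
      next
    }
    sub <- igraph::induced_subgraph(g, vs)
    wt <- igraph::cluster_walktrap(sub, steps = steps)
    mem <- as.integer(igraph::membership(wt))
    labels[vs] <- offset + mem
    offset <- offset + max(mem)
  }
  attr(labels, "K") <- offset
  labels
}

#' Cluster neurons from an event matrix
#'
#' Composition of \code{\link{build_neighbor_graph}} and
#' \code{\link{walktrap_partition}}: groups the P neurons into K homogeneous
#' clusters by trajectory similarity, with K chosen at the maximum-modularity
#' dendrogram cut.
#'
#' The neighbour count \code{k} controls the resolution of the graph and
#' should be comparable to the size of the smallest real neuron ensemble:
#' too small a k leaves large ensembles internally sparse (walktrap then
#' splits them), while a k exceeding the ensemble size forces every neuron to
#' adopt neighbours from the next-most-similar ensemble (walktrap then merges
#' the closest pair). Since ensemble sizes are unknown in advance, the
#' default \code{k = NULL} scans a grid of neighbour counts (every value from
#' 3 to 64, then doubling up to P-1) in increasing order and keeps the first
#' partition that is stable, i.e. reproduced exactly at the next neighbour
#' count on the grid; unstable partitions reflect arbitrary graph structure
#' rather than real ensembles. If no stable plateau exists the partition with
#' the highest mean silhouette (same Hamming trajectory metric) is returned.
#' Walktrap still selects K within each candidate graph, so this selects the
#' graph resolution, not the cluster count. Pass an explicit \code{k} to skip
#' the selection.
#'
#' @inheritParams build_neighbor_graph
#' @inheritParams walktrap_partition
#' @param k neighbours per neuron, or \code{NULL} (default) for automatic
#'   silhouette-based selection over a doubling grid.
#' @return An integer partition vector as from
#'   \code{\link{walktrap_partition}}, with attributes \code{"K"} and
#'   \code{"k"} (the neighbour count used).
#' @export
cluster_neurons <- function(E, k = NULL, steps = 4, approximate = FALSE,
                            seed = NULL) {
  v <- as_event_values(E)
  P <- nrow(v)
  if (P < 2L) stop("need at least 2 neurons to cluster")
  D <- hamming_dist(v)
  fit_one <- function(kk) {
    g <- knn_graph_from_dist(D, kk, approximate = approximate, seed = seed)
    igraph::V(g)$name <- rownames(v)
    walktrap_partition(g, steps = steps)
  }
  if (!is.null(k)) {
    part <- fit_one(k)
    attr(part, "k") <- as.integer(k)
    return(part)
  }
  # dense where cluster sizes are plausibly small, doubling beyond
  grid <- unique(pmin(c(3:64, 64L * 2L^(1:4)), P - 1L))
  grid <- grid[grid >= 1L]
  parts <- vector("list", length(grid))
  prev <- suppressWarnings(fit_one(grid[1L]))
  parts[[1L]] <- prev
  for (i in seq_along(grid)[-1L]) {
    cur <- suppressWarnings(fit_one(grid[i]))
    parts[[i]] <- cur
    if (rand_index(prev, cur) == 1) {   # stable plateau: keep its first k
      attr(prev, "k") <- grid[i - 1L]
      return(prev)
    }
    prev <- cur
  }
  # no plateau: fall back to the best-silhouette candidate
  best <- NULL
  best_sil <- -Inf
  for (i in seq_along(grid)) {
    part <- parts[[i]]
    sil <- if (attr(part, "K") < 2L) -Inf else mean_silhouette_dist(D, part)
    if (sil > best_sil) {
      best_sil <- sil
      best <- part
      attr(best, "k") <- grid[i]
    }
  }
  if (is.null(best)) {  # every candidate collapsed to one cluster
    best <- parts[[1L]]
    attr(best, "k") <- grid[1L]
  }
  best
}

# Mean silhouette width of a partition from a precomputed distance matrix.
mean_silhouette_dist <- function(D, part) {
  sil <- cluster::silhouette(as.integer(part), dmatrix = D)
  w <- sil[, "sil_width"]
  w[is.nan(w)] <- 0
  mean(w)
}

# Validate a partition against an event matrix; returns integer labels 1..K.
check_partition <- function(part, P) {
  part <- as.integer(part)
  if (length(part) != P)
    stop("partition length (", length(part),
         ") does not match neuron count (", P, ")")
  K <- max(part)
  if (min(part) < 1L || !all(seq_len(K) %in% part))
    stop("cluster labels must cover 1..K with every cluster non-empty")
  part
}

#' Read / write a partition as two-column delimited text
#'
#' Lines are \code{neuron_id<tab>cluster_id}.
#'
#' @param part integer partition vector named by neuron id.
#' @param path file path.
#' @return \code{write_partition}: \code{path}, invisibly.
#'   \code{read_partition}: a named integer partition vector.
#' @export
write_partition <- function(part, path) {
  ids <- names(part)
  if (is.null(ids)) ids <- paste0("n", seq_along(part))
  utils::write.table(data.frame(ids, as.integer(part)), path, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_partition
#' @export
read_partition <- function(path) {
  df <- utils::read.table(path, sep = detect_sep(path), header = FALSE,
                          colClasses = c("character", "integer"))
  part <- df[[2L]]
  names(part) <- df[[1L]]
  check_partition(part, length(part))
  attr(part, "K") <- max(part)
  part
}
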