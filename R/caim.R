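#' Fit a causal microcircuit model to neural ensemble activity
#'
#' The full inference pipeline on a binary neuronal event matrix: (1) group
#' neurons into K clusters by nearest-neighbour graph construction and
#' walktrap community detection, with K selected at the maximum-modularity
#' dendrogram cut; (2) infer binary cluster-state trajectories by thresholded
#' voting; (3) compute the neuron-by-cluster loading matrix of relative mutual
#' information; (4) learn the weighted directed two-slice temporal network
#' among cluster states from per-target random-forest variable importances.
#'
#' @param events an \code{\link{event_matrix}} (or plain P x T binary matrix).
#' @param k_neighbors neighbours per neuron in the k-NN graph; default
#'   \code{NULL} selects the neighbour count automatically by silhouette
#'   (see \code{\link{cluster_neurons}}).
#' @param walk_steps walktrap random-walk length (default 4).
#' @param threshold voting threshold for cluster-state inference
#'   (default 0.5, majority voting; strict inequality).
#' @param n_trees trees per target random forest (default 1000).
#' @param mtry predictors tried per split (default \code{ceiling(sqrt(K))}).
#' @param rmi_normalize normalization of the loading-matrix relative mutual
#'   information (see \code{\link{relative_mutual_information}}).
#' @param seed single seed governing the stochastic stages (the forests);
#'   clustering and state inference are deterministic.
#' @param loading compute the loading matrix (default TRUE; the P x K
#'   relative-MI computation is the slow part for very large P).
#' @return An object of class \code{"caim"}: a list with elements
#'   \code{partition} (named integer vector, attribute \code{"K"}),
#'   \code{K}, \code{graph} (the neighbour \code{igraph}), \code{states}
#'   (K x T binary matrix), \code{loading} (P x K matrix or NULL),
#'   \code{weights} (K x K \code{"caim_network"} matrix, \code{W[b, a]} =
#'   weight of link b at t -> a at t + 1), \code{config} and \code{call}.
#' @examples
#' dbn <- random_ground_truth(3, seed = 1)
#' Y <- sample_dbn(dbn, 400, seed = 2)
#' sim <- generate_neurons(Y, neurons_per_cluster = 6, lambda = 0.1, seed = 3)
#' fit <- caim(sim$events, k_neighbors = 4, n_trees = 50, seed = 4)
#' fit$K
#' coef(fit)
#' @export
caim <- function(events, k_neighbors = NULL, walk_steps = 4, threshold = 0.5,
                 n_trees = 1000, mtry = NULL, rmi_normalize = "min",
                 seed = NULL, loading = TRUE) {
  cl <- match.call()
  E <- event_matrix(events)
  part <- cluster_neurons(E, k = k_neighbors, steps = walk_steps)
  K <- attr(part, "K")
  k_used <- attr(part, "k")
  g <- build_neighbor_graph(E, k = k_used)
  Y <- infer_cluster_states(E, part, threshold = threshold)
  L <- if (loading) loading_matrix(E, Y, normalize = rmi_normalize) else NULL
  W <- if (K >= 2L) {
    infer_causal_network(Y, n_trees = n_trees, mtry = mtry, seed = seed)
  } else {
    warning("only one cluster detected; no network to infer")
    NULL
  }
  structure(list(partition = part, K = K, graph = g, states = Y,
                 loading = L, weights = W,
                 config = list(k_neighbors = k_used,
                               walk_steps = walk_steps,
                               threshold = threshold, n_trees = n_trees,
                               mtry = mtry, rmi_normalize = rmi_normalize,
                               seed = seed),
                 call = cl),
            class = "caim")
}

#' @export
print.caim <- function(x, ...) {
  cat("Causal microcircuit model\n")
  cat("  neurons:", length(x$partition),
      " frames:", ncol(x$states), "\n")
  cat("  clusters detected:", x$K,
      " (sizes:", paste(as.vector(table(x$partition)), collapse = ", "),
      ")\n")
  if (!is.null(x$weights)) {
    sl <- strong_links(x$weights)
    cat("  strong links (weight > median):", nrow(sl), "\n")
  }
  invisible(x)
}

#' @export
summary.caim <- function(object, ...) {
  x <- object
  mod <- tryCatch(
    igraph::modularity(x$graph, igraph::membership(
      igraph::make_clusters(x$graph, as.integer(x$partition)))),
    error = function(e) NA_real_)
  within_between <- if (!is.null(x$loading)) {
    own <- matrix(FALSE, nrow(x$loading), ncol(x$loading))
    own[cbind(seq_along(x$partition), as.integer(x$partition))] <- TRUE
    c(within = mean(x$loading[own]),
      between = if (x$K > 1L) mean(x$loading[!own]) else NA_real_)
  } else c(within = NA_real_, between = NA_real_)
  out <- list(
    n_neurons = length(x$partition),
    n_frames = ncol(x$states),
    K = x$K,
    cluster_sizes = as.vector(table(x$partition)),
    modularity = mod,
    state_occupancy = rowMeans(x$states),
    loading_within = within_between[["within"]],
    loading_between = within_between[["between"]],
    strong_links = if (!is.null(x$weights)) strong_links(x$weights) else NULL,
    config = x$config
  )
  class(out) <- "summary.caim"
  out
}

#' @export
print.summary.caim <- function(x, ...) {
  cat("Causal microcircuit model summary\n")
  cat(sprintf("  %d neurons x %d frames -> %d clusters (sizes %s)\n",
              x$n_neurons, x$n_frames, x$K,
              paste(x$cluster_sizes, collapse = ", ")))
  if (!is.na(x$modularity))
    cat(sprintf("  neighbour-graph modularity: %.3f\n", x$modularity))
  cat("  cluster-state occupancy:",
      paste(signif(x$state_occupancy, 3), collapse = ", "), "\n")
  if (!is.na(x$loading_within))
    cat(sprintf("  mean loading within/between cluster: %.3f / %.3f\n",
                x$loading_within, x$loading_between))
  if (!is.null(x$strong_links)) {
    cat("  strong links (weight > median of all weights):\n")
    print(x$strong_links, row.names = FALSE)
  }
  invisible(x)
}

#' @export
coef.caim <- function(object, ...) {
  object$weights
}

#' Plot a fitted causal microcircuit model
#'
#' Draws the inferred cluster network as a directed graph (edge width
#' proportional to weight, strong links solid, others dashed) and, when
#' available, the loading matrix as an image with neurons ordered by cluster.
#'
#' @param x a \code{\link{caim}} fit.
#' @param which \code{"network"}, \code{"loading"}, or \code{"both"}.
#' @param ... passed to \code{igraph::plot.igraph}.
#' @return \code{x}, invisibly.
#' @export
plot.caim <- function(x, which = c("both", "network", "loading"), ...) {
  which <- match.arg(which)
  do_net <- which %in% c("both", "network") && !is.null(x$weights)
  do_load <- which %in% c("both", "loading") && !is.null(x$loading)
  if (do_net && do_load) {
    op <- graphics::par(mfrow = c(1, 2))
    on.exit(graphics::par(op))
  }
  if (do_net) {
    W <- unclass(x$weights)
    g <- igraph::graph_from_adjacency_matrix(W, mode = "directed",
                                             weighted = TRUE, diag = TRUE)
    med <- stats::median(W)
    ew <- igraph::E(g)$weight
    igraph::plot.igraph(
      g,
      edge.width = 1 + 4 * ew / max(ew),
      edge.lty = ifelse(ew > med, 1, 2),
      edge.curved = 0.2,
      main = "Inferred cluster network", ...)
  }
  if (do_load) {
    ord <- order(x$partition)
    graphics::image(t(x$loading[ord, , drop = FALSE]),
                    axes = FALSE, col = grDevices::hcl.colors(64, "YlOrRd",
                                                              rev = TRUE),
                    main = "Loading matrix", xlab = "cluster",
                    ylab = "neuron (by cluster)")
  }
  invisible(x)
}
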