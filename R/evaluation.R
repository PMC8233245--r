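#' Rand index between two partitions
#'
#' Fraction of unordered object pairs on which the two partitions agree
#' (both place the pair together, or both apart). Plain (unadjusted) Rand:
#' 1 means perfect agreement up to label renaming.
#'
#' @param p1,p2 cluster label vectors of equal length (any label coding).
#' @return A number in \code{[0, 1]}.
#' @examples
#' rand_index(c(1, 1, 2, 2), c(1, 2, 1, 2))  # 2/6
#' @export
rand_index <- function(p1, p2) {
  if (length(p1) != length(p2))
    stop("partitions have different lengths: ",
         length(p1), " vs ", length(p2))
  n <- length(p1)
  if (n < 2L) stop("need at least 2 objects")
  tab <- table(p1, p2)
  # pair-counting identity: agreements from the contingency table
  sum_ij <- sum(choose(tab, 2))
  sum_i <- sum(choose(rowSums(tab), 2))
  sum_j <- sum(choose(colSums(tab), 2))
  total <- choose(n, 2)
  (total + 2 * sum_ij - sum_i - sum_j) / total
}

#' Mean silhouette score of a partition of neuron trajectories
#'
#' Standard silhouette: for object i with mean intra-cluster distance a and
#' smallest mean distance to another cluster b, the score is
#' \code{(b - a) / max(a, b)}; objects in singleton clusters score 0, and
#' \code{a = b = 0} scores 0. Distances are Hamming between binary rows, the
#' same trajectory metric the clustering uses.
#'
#' @param E an \code{\link{event_matrix}} (or plain binary matrix), P x T.
#' @param part integer partition with labels \code{1..K}, K >= 2, every
#'   cluster non-empty.
#' @return The mean silhouette over objects, in \code{[-1, 1]}.
#' @export
silhouette_score <- function(E, part) {
  v <- as_event_values(E)
  part <- check_partition(part, nrow(v))
  if (max(part) < 2L) stop("silhouette needs at least 2 clusters")
  sil <- cluster::silhouette(part, stats::dist(v, method = "manhattan"))
  widths <- sil[, "sil_width"]
  widths[is.nan(widths)] <- 0        # a = b = 0 convention
  mean(widths)
}

#' Edge-recovery AUC of a weighted graph against a ground truth
#'
#' Rank-based (Mann-Whitney) area under the ROC curve: the probability that a
#' uniformly chosen true edge receives a higher inferred weight than a
#' uniformly chosen non-edge, with ties counting one half (midranks). It is
#' threshold-free and invariant to strictly monotone transforms of the
#' weights.
#'
#' @param W K x K inferred weight matrix, \code{W[b, a]} the weight of link
#'   b -> a.
#' @param truth K x K binary matrix of true links, same node order.
#' @param include_self whether self links enter the positive/negative sets.
#'   Default \code{NA} excludes them when the truth places no self links and
#'   includes them otherwise.
#' @return AUC in \code{[0, 1]}.
#' @export
edge_auc <- function(W, truth, include_self = NA) {
  W <- unclass(W)
  if (!is.matrix(W) || !is.matrix(truth) || !all(dim(W) == dim(truth)) ||
      nrow(W) != ncol(W))
    stop("W and truth must be square matrices of identical shape")
  if (anyNA(truth) || !all(truth == 0L | truth == 1L))
    stop("truth entries must all be 0 or 1")
  if (is.na(include_self)) include_self <- any(diag(truth) == 1L)
  keep <- if (include_self) rep(TRUE, length(W)) else !diag(nrow(W))
  w <- W[keep]
  y <- truth[keep]
  n1 <- sum(y == 1L); n0 <- sum(y == 0L)
  if (n1 == 0L || n0 == 0L)
    stop("truth must contain at least one edge and one non-edge")
  r <- rank(w)                       # midranks handle ties
  (sum(r[y == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Match detected cluster labels to reference labels
#'
#' Maps each detected cluster to the reference cluster with which it shares
#' the most members (majority overlap, ties to the lower reference label).
#' Useful for reordering an inferred weight matrix into the node order of a
#' ground-truth graph before computing \code{\link{edge_auc}}.
#'
#' @param part detected integer partition.
#' @param reference ground-truth partition of the same objects.
#' @return An integer vector of length \code{max(part)}: entry k is the
#'   reference label matched to detected cluster k.
#' @export
match_partition_labels <- function(part, reference) {
  if (length(part) != length(reference))
    stop("partitions have different lengths")
  tab <- table(part, reference)
  apply(tab, 1L, which.max)
}
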