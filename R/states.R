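#' Infer binary cluster states by thresholded voting
#'
#' For each cluster A and frame t, computes the fraction of cluster-A neurons
#' with an event at t; the cluster state is 1 when that fraction strictly
#' exceeds \code{threshold}. The default 0.5 is majority voting; higher
#' thresholds give sparser cluster activation.
#'
#' @param E an \code{\link{event_matrix}} (or plain binary matrix).
#' @param part integer partition vector with labels in \code{1..K}, length P.
#' @param threshold voting threshold in \code{[0, 1]} (default 0.5). The
#'   comparison is strict, so \code{threshold = 1} yields all-zero states and
#'   \code{threshold = 0} marks any frame with at least one active neuron.
#' @return A K x T binary integer matrix of cluster states with rownames
#'   \code{"c1" ... "cK"}.
#' @examples
#' E <- event_matrix(rbind(c(1, 0), c(1, 0), c(0, 1), c(1, 1)))
#' infer_cluster_states(E, c(1, 1, 2, 2))
#' @export
infer_cluster_states <- function(E, part, threshold = 0.5) {
  v <- as_event_values(E)
  part <- check_partition(part, nrow(v))
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      threshold < 0 || threshold > 1)
    stop("threshold must be a single number in [0, 1]")
  K <- max(part)
  frac <- rowsum(v, part) / as.vector(table(part))
  Y <- matrix(as.integer(frac > threshold), nrow = K,
              dimnames = list(paste0("c", seq_len(K)), NULL))
  Y
}

#' Relative mutual information between two binary series
#'
#' Plug-in mutual information of the empirical joint distribution of two
#' equal-length binary series, normalized into \code{[0, 1]}. The default
#' normalization divides by the smaller of the two marginal entropies, which
#' guarantees the unit range and gives 1 for identical (or complementary)
#' non-constant series; when either series is constant the score is 0 by
#' convention. Mutual information is computed in nats; the normalization makes
#' the logarithm base irrelevant.
#'
#' @param x,y binary vectors of equal length >= 1.
#' @param normalize normalization denominator: \code{"min"} (default) for
#'   \code{min(H(x), H(y))}, \code{"max"} for \code{max(H(x), H(y))},
#'   \code{"hy"} for \code{H(y)}.
#' @return A single number in \code{[0, 1]}, symmetric in \code{x} and
#'   \code{y} for \code{"min"}/\code{"max"}.
#' @examples
#' x <- rbinom(1000, 1, 0.5)
#' relative_mutual_information(x, x)        # 1
#' relative_mutual_information(x, rep(0, 1000))  # 0
#' @export
relative_mutual_information <- function(x, y,
                                        normalize = c("min", "max", "hy")) {
  normalize <- match.arg(normalize)
  if (length(x) != length(y))
    stop("series lengths differ: ", length(x), " vs ", length(y))
  if (length(x) < 1L) stop("series must have length >= 1")
  if (anyNA(x) || anyNA(y) || !all(x %in% 0:1) || !all(y %in% 0:1))
    stop("series must be binary (0/1) with no missing values")
  n <- length(x)
  # joint counts of the 2x2 table
  n11 <- sum(x == 1L & y == 1L)
  n10 <- sum(x == 1L) - n11
  n01 <- sum(y == 1L) - n11
  n00 <- n - n11 - n10 - n01
  pj <- c(n00, n01, n10, n11) / n
  px <- c(n00 + n01, n10 + n11) / n
  py <- c(n00 + n10, n01 + n11) / n
  hx <- plugin_entropy(px)
  hy <- plugin_entropy(py)
  denom <- switch(normalize, min = min(hx, hy), max = max(hx, hy), hy = hy)
  if (denom <= 0) return(0)
  mi <- plugin_entropy(px) + plugin_entropy(py) - plugin_entropy(pj)
  # guard against floating-point excursions outside [0, denom]
  min(max(mi, 0), denom) / denom
}

plugin_entropy <- function(p) {
  p <- p[p > 0]
  -sum(p * log(p))
}

#' Neuron-by-cluster loading matrix
#'
#' Quantifies the association between every neuron and every cluster-state
#' variable: entry \code{(i, j)} is the relative mutual information between
#' the trajectory of neuron i and the state series of cluster j. High loadings
#' concentrated in a neuron's own cluster column indicate good cluster
#' separation.
#'
#' @param E an \code{\link{event_matrix}} (or plain binary matrix), P x T.
#' @param Y a K x T binary cluster-state matrix from
#'   \code{\link{infer_cluster_states}}.
#' @param normalize passed to \code{\link{relative_mutual_information}}.
#' @return A P x K numeric matrix in \code{[0, 1]} with neuron ids as rownames
#'   and cluster ids as colnames.
#' @export
loading_matrix <- function(E, Y, normalize = "min") {
  v <- as_event_values(E)
  Y <- check_state_matrix(Y)
  if (ncol(v) != ncol(Y))
    stop("event matrix and state matrix disagree on T: ",
         ncol(v), " vs ", ncol(Y))
  L <- matrix(0, nrow(v), nrow(Y),
              dimnames = list(rownames(v), rownames(Y)))
  for (j in seq_len(nrow(Y)))
    for (i in seq_len(nrow(v)))
      L[i, j] <- relative_mutual_information(v[i, ], Y[j, ],
                                             normalize = normalize)
  L
}

# Validate a K x T binary state matrix.
check_state_matrix <- function(Y) {
  if (!is.matrix(Y)) Y <- as.matrix(Y)
  if (anyNA(Y) || !all(Y == 0L | Y == 1L))
    stop("cluster state matrix entries must all be 0 or 1")
  storage.mode(Y) <- "integer"
  if (is.null(rownames(Y))) rownames(Y) <- paste0("c", seq_len(nrow(Y)))
  Y
}

#' Write / read a labelled binary state matrix
#'
#' Same layout as event matrices: first column the cluster id, remaining
#' columns the 0/1 state per frame.
#'
#' @param Y K x T binary matrix.
#' @param path file path.
#' @return \code{write_state_matrix}: \code{path} invisibly;
#'   \code{read_state_matrix}: a K x T binary integer matrix.
#' @export
write_state_matrix <- function(Y, path) {
  Y <- check_state_matrix(Y)
  out <- cbind(rownames(Y), as.data.frame(Y))
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_state_matrix
#' @export
read_state_matrix <- function(path) {
  m <- read_event_matrix(path)
  Y <- unclass(m)
  attr(Y, "frame_ms") <- NULL
  class(Y) <- NULL
  storage.mode(Y) <- "integer"
  Y
}
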