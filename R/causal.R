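#' First-order lagged design over cluster states
#'
#' Arranges a K x T cluster-state matrix as a two-slice design: predictor row
#' t holds the full state vector at time t, and the response for target
#' cluster a at that row is the state of a at time t + 1. The transition model
#' learned on this design is a two-slice temporal Bayesian network (first
#' order, time invariant).
#'
#' @param Y a K x T binary cluster-state matrix, T >= 2.
#' @return A list of class \code{"lagged_design"} with elements
#'   \code{predictors} ((T-1) x K matrix of states at t) and
#'   \code{responses} ((T-1) x K matrix of states at t + 1).
#' @examples
#' Y <- rbind(c1 = c(1, 0, 1, 0))
#' d <- make_lagged_design(Y)
#' d$predictors[, 1]  # 1 0 1
#' d$responses[, 1]   # 0 1 0
#' @export
make_lagged_design <- function(Y) {
  Y <- check_state_matrix(Y)
  T_ <- ncol(Y)
  if (T_ < 2L) stop("need at least 2 time points to form a lagged design")
  X <- t(Y[, -T_, drop = FALSE])
  R <- t(Y[, -1L, drop = FALSE])
  colnames(X) <- rownames(Y)
  colnames(R) <- rownames(Y)
  structure(list(predictors = X, responses = R), class = "lagged_design")
}

#' Random-forest variable importances for one target cluster
#'
#' Fits a regression random forest predicting the state of \code{target} at
#' t + 1 from all cluster states at t (bootstrap sample per tree, random
#' predictor subset per split node) and extracts, for each predictor, the
#' split variance reduction summed within each tree and averaged over trees.
#' The importances are then normalized to sum to 1, making weights comparable
#' across targets. Regression (variance-reduction) trees are used on the 0/1
#' response rather than classification trees.
#'
#' A constant response carries no variance to reduce: the function returns an
#' all-zero vector (no normalization) with a warning, so recordings with
#' silent clusters still run.
#'
#' @param design a \code{\link{make_lagged_design}} result.
#' @param target target cluster: index or name of a column of the design.
#' @param n_trees number of trees (default 1000).
#' @param mtry size of the random predictor subset per split; default
#'   \code{ceiling(sqrt(K))}.
#' @param seed optional RNG seed for exact reproducibility.
#' @return A named numeric length-K importance vector, entries >= 0; sums to 1
#'   unless the response is constant.
#' @export
target_importances <- function(design, target, n_trees = 1000, mtry = NULL,
                               seed = NULL) {
  stopifnot(inherits(design, "lagged_design"))
  n_trees <- as.integer(n_trees)
  if (n_trees < 1L) stop("n_trees must be >= 1")
  X <- design$predictors
  K <- ncol(X)
  if (is.character(target)) target <- match(target, colnames(X))
  if (is.na(target) || target < 1L || target > K)
    stop("unknown target cluster")
  y <- as.numeric(design$responses[, target])
  out <- stats::setNames(numeric(K), colnames(X))
  if (length(unique(y)) == 1L) {
    warning("response of target '", colnames(X)[target],
            "' is constant; returning zero importances")
    return(out)
  }
  if (is.null(mtry)) mtry <- ceiling(sqrt(K))
  mtry <- min(as.integer(mtry), K)
  if (!is.null(seed)) set.seed(seed)
  rf <- withCallingHandlers(
    randomForest::randomForest(
      x = as.data.frame(X), y = y,
      ntree = n_trees, mtry = mtry, replace = TRUE,
      importance = FALSE
    ),
    # regression on a 0/1 response is deliberate (variance-reduction splits)
    warning = function(w) {
      if (grepl("five or fewer unique values", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  imp <- rf$importance[, "IncNodePurity"]
  imp[imp < 0] <- 0
  s <- sum(imp)
  if (s > 0) imp <- imp / s
  out[] <- imp
  out
}

#' Infer a weighted directed causal network over cluster states
#'
#' For every target cluster a, fits a random-forest regression of the state of
#' a at t + 1 on all cluster states at t and uses the variable importance of
#' cluster b as the weight of the directed link b -> a. Self links (state
#' persistence) are candidate predictors like any other. Higher weight means a
#' stronger putative causal relationship; the result is the weighted adjacency
#' of the two-slice temporal network.
#'
#' @param Y a K x T binary cluster-state matrix, K >= 2, T >= 2.
#' @param n_trees trees per target forest (default 1000).
#' @param mtry random predictor subset size per split; default
#'   \code{ceiling(sqrt(K))}.
#' @param seed optional seed; per-target seeds are derived deterministically
#'   from it so results are reproducible bit for bit.
#' @return A K x K numeric matrix \code{W} of class \code{"caim_network"}
#'   with \code{W[b, a]} the weight of the link b (at t) -> a (at t + 1);
#'   non-degenerate columns sum to 1.
#' @export
infer_causal_network <- function(Y, n_trees = 1000, mtry = NULL, seed = NULL) {
  Y <- check_state_matrix(Y)
  K <- nrow(Y)
  if (K < 2L) stop("need at least 2 clusters to infer a network")
  design <- make_lagged_design(Y)
  W <- matrix(0, K, K, dimnames = list(rownames(Y), rownames(Y)))
  for (a in seq_len(K)) {
    s_a <- if (is.null(seed)) NULL else derive_seed(seed, a)
    W[, a] <- target_importances(design, a, n_trees = n_trees, mtry = mtry,
                                 seed = s_a)
  }
  class(W) <- c("caim_network", class(W))
  W
}

# Deterministic per-stage seed expansion of a single user seed.
derive_seed <- function(seed, stage) {
  as.integer((as.numeric(seed) * 48271 + 1000003 * stage) %%
               .Machine$integer.max)
}

#' @export
print.caim_network <- function(x, ...) {
  K <- nrow(x)
  cat("Weighted directed cluster network:", K, "nodes,",
      K * K, "candidate links\n")
  sl <- strong_links(x)
  cat("Strong links (weight > median):", nrow(sl), "\n")
  if (nrow(sl)) print(sl, row.names = FALSE)
  invisible(x)
}

#' Strong links of a weighted cluster network
#'
#' Returns the edges whose weight strictly exceeds the median of all K^2
#' weights (self links included in both the median and the candidate set).
#' With all weights equal, nothing exceeds the median and the set is empty.
#'
#' @param W a K x K weight matrix as from \code{\link{infer_causal_network}},
#'   with \code{W[b, a]} the weight of link b -> a.
#' @return A data frame with columns \code{from}, \code{to}, \code{weight},
#'   sorted by decreasing weight.
#' @export
strong_links <- function(W) {
  W <- unclass(W)
  if (!is.matrix(W) || nrow(W) != ncol(W))
    stop("W must be a square weight matrix")
  if (is.null(rownames(W))) {
    rownames(W) <- colnames(W) <- paste0("c", seq_len(nrow(W)))
  }
  med <- stats::median(W)
  idx <- which(W > med, arr.ind = TRUE)
  out <- data.frame(
    from = rownames(W)[idx[, 1L]],
    to = colnames(W)[idx[, 2L]],
    weight = W[idx],
    stringsAsFactors = FALSE
  )
  out[order(-out$weight), , drop = FALSE]
}

#' Write / read a weighted edge list
#'
#' Three-column delimited text: source, target, weight (one line per ordered
#' pair, fixed row-major order so identical networks serialize identically).
#'
#' @param W K x K weight matrix.
#' @param path file path.
#' @param strong_only if TRUE write only \code{\link{strong_links}}.
#' @return \code{write_edge_list}: \code{path} invisibly;
#'   \code{read_edge_list}: a K x K weight matrix of class
#'   \code{"caim_network"}.
#' @export
write_edge_list <- function(W, path, strong_only = FALSE) {
  if (strong_only) {
    df <- strong_links(W)
  } else {
    W <- unclass(W)
    df <- data.frame(
      from = rep(rownames(W), times = ncol(W)),
      to = rep(colnames(W), each = nrow(W)),
      weight = as.vector(W)
    )
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_edge_list
#' @export
read_edge_list <- function(path) {
  df <- utils::read.table(path, sep = detect_sep(path), header = FALSE,
                          col.names = c("from", "to", "weight"),
                          colClasses = c("character", "character", "numeric"))
  nodes <- unique(c(df$from, df$to))
  W <- matrix(0, length(nodes), length(nodes),
              dimnames = list(nodes, nodes))
  W[cbind(df$from, df$to)] <- df$weight
  class(W) <- c("caim_network", class(W))
  W
}
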