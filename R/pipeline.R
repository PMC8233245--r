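#' Run the full analysis pipeline and write every artifact
#'
#' End-to-end orchestration: read (or accept) an event matrix, fit the
#' causal microcircuit model, optionally evaluate against ground truth, and
#' write partition, cluster states, loading matrix, edge list, strong links,
#' metrics and a run log to \code{out_dir}. Outputs are written to a
#' temporary staging directory and moved into place only on success, so a
#' failed run leaves no partial artifacts in the final location. Identical
#' config and seed reproduce byte-identical outputs.
#'
#' @param events path to a delimited event-matrix file, or an
#'   \code{\link{event_matrix}} / binary matrix.
#' @param out_dir output directory (created if missing).
#' @param k_neighbors,walk_steps,threshold,n_trees,seed model parameters, see
#'   \code{\link{caim}}.
#' @param truth_partition optional ground-truth labels (vector or path to a
#'   two-column file) for Rand/silhouette metrics.
#' @param truth_graph optional ground-truth K x K binary adjacency (matrix or
#'   path to an edge-list file) for edge-recovery AUC.
#' @return Invisibly, a list with the fitted \code{model}, computed
#'   \code{metrics} and the vector of written \code{files}.
#' @export
run_pipeline <- function(events, out_dir,
                         k_neighbors = NULL, walk_steps = 4, threshold = 0.5,
                         n_trees = 1000, seed = 1,
                         truth_partition = NULL, truth_graph = NULL) {
  t0 <- Sys.time()
  E <- if (is.character(events)) read_event_matrix(events)
       else event_matrix(events)
  if (is.character(truth_partition))
    truth_partition <- read_partition(truth_partition)
  if (is.character(truth_graph)) truth_graph <- read_edge_list(truth_graph)

  fit <- caim(E, k_neighbors = k_neighbors, walk_steps = walk_steps,
              threshold = threshold, n_trees = n_trees, seed = seed)

  metrics <- list(K = fit$K)
  if (!is.null(truth_partition)) {
    metrics$rand_index <- rand_index(fit$partition, truth_partition)
    metrics$silhouette <- tryCatch(silhouette_score(E, fit$partition),
                                   error = function(e) NA_real_)
  }
  if (!is.null(truth_graph) && !is.null(fit$weights) &&
      nrow(truth_graph) == fit$K) {
    metrics$edge_auc <- edge_auc(fit$weights, unclass(truth_graph) > 0)
  }

  stage <- tempfile("caim_stage_")
  dir.create(stage, recursive = TRUE)
  ok <- FALSE
  on.exit(if (!ok) unlink(stage, recursive = TRUE))

  write_partition(fit$partition, file.path(stage, "partition.tsv"))
  write_state_matrix(fit$states, file.path(stage, "states.tsv"))
  if (!is.null(fit$loading))
    utils::write.table(round(fit$loading, 6), file.path(stage, "loading.tsv"),
                       sep = "\t", quote = FALSE, col.names = NA)
  if (!is.null(fit$weights)) {
    write_edge_list(fit$weights, file.path(stage, "edges.tsv"))
    write_edge_list(fit$weights, file.path(stage, "strong_links.tsv"),
                    strong_only = TRUE)
  }
  mdf <- data.frame(metric = names(metrics),
                    value = unlist(lapply(metrics, format, digits = 10)))
  utils::write.table(mdf, file.path(stage, "metrics.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  log_lines <- c(
    paste0("caim version: ",
           as.character(utils::packageVersion("caim"))),
    paste0("R version: ", R.version.string),
    paste0("config: k_neighbors=", fit$config$k_neighbors,
           " walk_steps=", walk_steps,
           " threshold=", threshold, " n_trees=", n_trees, " seed=", seed),
    paste0("neurons=", length(fit$partition), " frames=", ncol(fit$states),
           " clusters=", fit$K),
    paste0("elapsed_s=",
           format(as.numeric(difftime(Sys.time(), t0, units = "secs")),
                  digits = 4)))
  writeLines(log_lines, file.path(stage, "run.log"))

  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  files <- list.files(stage)
  for (f in files)
    if (!file.copy(file.path(stage, f), file.path(out_dir, f),
                   overwrite = TRUE))
      stop("failed to move artifact ", f, " into ", out_dir)
  ok <- TRUE
  unlink(stage, recursive = TRUE)
  invisible(list(model = fit, metrics = metrics,
                 files = file.path(out_dir, files)))
}

#' Simulate a labelled spike-train dataset from a random ground-truth network
#'
#' Convenience wrapper chaining \code{\link{random_ground_truth}},
#' \code{\link{sample_dbn}} and \code{\link{generate_neurons}} under one seed,
#' producing a dataset with known partition and known transition structure.
#'
#' @param K number of clusters.
#' @param T_len number of time points (default 5000).
#' @param neurons_per_cluster neurons per cluster (default 10).
#' @param lambda per-frame flip-noise probability (default 0.2).
#' @param seed single seed; sub-stage seeds are derived deterministically.
#' @param parents_range parent-set sizes for the ground truth; the default
#'   1 to \code{min(3, K - 1)} keeps the draw feasible for small K.
#' @param ... further arguments to \code{\link{random_ground_truth}}.
#' @return A list with \code{events}, \code{partition}, \code{states},
#'   \code{dbn} and \code{truth} (the K x K binary adjacency).
#' @export
simulate_dbn_dataset <- function(K, T_len = 5000, neurons_per_cluster = 10,
                                 lambda = 0.2, seed = 1,
                                 parents_range = c(1, min(3, K - 1)), ...) {
  dbn <- random_ground_truth(K, parents_range = parents_range,
                             seed = derive_seed(seed, 1L), ...)
  Y <- sample_dbn(dbn, T_len, seed = derive_seed(seed, 2L))
  gen <- generate_neurons(Y, neurons_per_cluster = neurons_per_cluster,
                          lambda = lambda, seed = derive_seed(seed, 3L))
  list(events = gen$events, partition = gen$partition, states = Y,
       dbn = dbn, truth = dbn_adjacency(dbn))
}
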