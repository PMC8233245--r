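#' Binary neuronal event matrix
#'
#' Construct and validate a P x T matrix of binary neuronal events, the basic
#' data container of the package. Entry \code{(i, t) = 1} records an event
#' (spike or calcium transient) of neuron \code{i} at frame \code{t}.
#'
#' @param values numeric or integer matrix with entries in \{0, 1\}; rows are
#'   neurons, columns are time frames.
#' @param neuron_ids optional character vector of unique neuron labels, one per
#'   row. Defaults to existing rownames or \code{"n1" ... "nP"}.
#' @param frame_ms optional positive duration of one frame in milliseconds,
#'   kept as an attribute for provenance (e.g. the bin width used by
#'   \code{\link{bin_spikes}}).
#'
#' @return An integer matrix of class \code{"event_matrix"} with neuron ids as
#'   rownames and, when known, a \code{"frame_ms"} attribute.
#' @examples
#' E <- event_matrix(rbind(c(0, 1, 1), c(1, 0, 0)))
#' dim(E)
#' @export
event_matrix <- function(values, neuron_ids = NULL, frame_ms = NULL) {
  if (!is.matrix(values)) values <- as.matrix(values)
  if (nrow(values) < 1L || ncol(values) < 2L)
    stop("event matrix needs at least 1 neuron and 2 time frames, got ",
         nrow(values), " x ", ncol(values))
  if (anyNA(values) || !all(values == 0L | values == 1L))
    stop("event matrix entries must all be 0 or 1")
  storage.mode(values) <- "integer"
  if (is.null(neuron_ids)) neuron_ids <- rownames(values)
  if (is.null(neuron_ids)) neuron_ids <- paste0("n", seq_len(nrow(values)))
  neuron_ids <- as.character(neuron_ids)
  if (length(neuron_ids) != nrow(values))
    stop("neuron_ids length (", length(neuron_ids),
         ") does not match number of rows (", nrow(values), ")")
  if (anyDuplicated(neuron_ids))
    stop("neuron_ids must be unique")
  rownames(values) <- neuron_ids
  if (!is.null(frame_ms)) {
    if (!is.numeric(frame_ms) || length(frame_ms) != 1L || frame_ms <= 0)
      stop("frame_ms must be a single positive number")
    attr(values, "frame_ms") <- as.numeric(frame_ms)
  }
  class(values) <- c("event_matrix", class(values))
  values
}

#' @export
print.event_matrix <- function(x, ...) {
  cat("Binary event matrix:", nrow(x), "neurons x", ncol(x), "frames\n")
  if (!is.null(attr(x, "frame_ms")))
    cat("Frame duration:", attr(x, "frame_ms"), "ms\n")
  cat("Event rate:", signif(mean(x), 3), "(fraction of active entries)\n")
  invisible(x)
}

# Strip class/attributes down to a plain validated binary integer matrix.
as_event_values <- function(E) {
  if (inherits(E, "event_matrix")) return(unclass(E))
  unclass(event_matrix(E))
}

#' Read a binary event matrix from delimited text
#'
#' Expected layout: one row per neuron, first column the neuron id, remaining
#' columns the 0/1 event indicator per frame. Tab and comma delimiters are
#' auto-detected (tab is what \code{\link{write_event_matrix}} emits).
#'
#' @param path path to a delimited text file.
#' @param sep field delimiter; \code{NULL} (default) auto-detects "\\t" vs ",".
#' @param frame_ms optional frame duration in ms, attached to the result.
#' @return An \code{\link{event_matrix}}.
#' @export
read_event_matrix <- function(path, sep = NULL, frame_ms = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(sep)) sep <- detect_sep(path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) < 1L) stop("parse error in ", path, ": file is empty")
  fields <- strsplit(lines, sep, fixed = TRUE)
  ncols <- lengths(fields)
  if (any(ncols != ncols[1L]))
    stop("parse error in ", path, ": line ", which(ncols != ncols[1L])[1L],
         " has ", ncols[which(ncols != ncols[1L])[1L]],
         " fields, expected ", ncols[1L])
  if (ncols[1L] < 3L)
    stop("parse error in ", path, ": need an id column plus at least 2 frames")
  ids <- vapply(fields, `[[`, character(1L), 1L)
  vals <- lapply(fields, function(f) suppressWarnings(as.numeric(f[-1L])))
  bad <- which(vapply(vals, anyNA, logical(1L)))
  if (length(bad))
    stop("parse error in ", path, ": non-numeric entry on line ", bad[1L])
  m <- do.call(rbind, vals)
  nonbin <- which(apply(m != 0 & m != 1, 1L, any))
  if (length(nonbin))
    stop("validation error in ", path, ": entry not in {0,1} on line ",
         nonbin[1L])
  event_matrix(m, neuron_ids = ids, frame_ms = frame_ms)
}

#' Write a binary event matrix to tab-delimited text
#'
#' @param E an \code{\link{event_matrix}} (or plain binary matrix).
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_event_matrix <- function(E, path) {
  E <- event_matrix(E)
  out <- cbind(rownames(E), as.data.frame(unclass(E)))
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

detect_sep <- function(path) {
  first <- readLines(path, n = 1L)
  if (grepl("\t", first, fixed = TRUE)) "\t" else ","
}

#' Per-neuron spike time lists
#'
#' Container for simultaneously recorded spike trains: a named list of
#' non-decreasing spike times in milliseconds plus the recording duration.
#'
#' @param times list of numeric vectors of spike times (ms), one per neuron;
#'   names are neuron ids (defaults to \code{"n1" ...}). Times must lie in
#'   \code{[0, duration_ms)}.
#' @param duration_ms total recording duration in ms (single positive number).
#' @return A list of class \code{"spike_train_set"} with elements
#'   \code{times} (each vector sorted) and \code{duration_ms}.
#' @export
spike_train_set <- function(times, duration_ms) {
  if (!is.list(times) || length(times) < 1L)
    stop("times must be a non-empty list of spike-time vectors")
  if (!is.numeric(duration_ms) || length(duration_ms) != 1L || duration_ms <= 0)
    stop("duration_ms must be a single positive number")
  if (is.null(names(times))) names(times) <- paste0("n", seq_along(times))
  if (anyDuplicated(names(times))) stop("neuron ids must be unique")
  times <- lapply(times, function(tt) {
    tt <- as.numeric(tt)
    if (anyNA(tt)) stop("spike times must be numeric and non-missing")
    if (length(tt) && (min(tt) < 0 || max(tt) >= duration_ms))
      stop("spike times must lie in [0, duration_ms)")
    sort(tt)
  })
  structure(list(times = times, duration_ms = as.numeric(duration_ms)),
            class = "spike_train_set")
}

#' @export
print.spike_train_set <- function(x, ...) {
  n <- lengths(x$times)
  cat("Spike train set:", length(x$times), "neurons,",
      x$duration_ms, "ms\n")
  cat("Spike counts: min", min(n), "median", stats::median(n),
      "max", max(n), "\n")
  invisible(x)
}

#' Read spike times from two-column delimited text
#'
#' Each line is \code{neuron_id<sep>time_ms}. Neurons appear in order of first
#' occurrence; an optional \code{neuron_ids} argument forces the roster (so
#' silent neurons are kept with empty trains).
#'
#' @param path input file path.
#' @param duration_ms recording duration in ms.
#' @param sep delimiter; auto-detected when \code{NULL}.
#' @param neuron_ids optional character vector fixing the neuron roster/order.
#' @return A \code{\link{spike_train_set}}.
#' @export
read_spike_times <- function(path, duration_ms, sep = NULL, neuron_ids = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(sep)) sep <- detect_sep(path)
  df <- utils::read.table(path, sep = sep, header = FALSE,
                          colClasses = c("character", "numeric"),
                          col.names = c("id", "t"))
  ids <- if (is.null(neuron_ids)) unique(df$id) else as.character(neuron_ids)
  times <- lapply(ids, function(i) df$t[df$id == i])
  names(times) <- ids
  spike_train_set(times, duration_ms)
}

#' Write spike times as two-column delimited text
#'
#' @param spikes a \code{\link{spike_train_set}}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_spike_times <- function(spikes, path) {
  stopifnot(inherits(spikes, "spike_train_set"))
  df <- data.frame(
    id = rep(names(spikes$times), lengths(spikes$times)),
    t = unlist(spikes$times, use.names = FALSE)
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Bin spike trains into a binary event matrix
#'
#' Non-overlapping bins of width \code{bin_ms}; bin \code{b} covers the
#' half-open interval \code{[(b-1) w, b w)}, so a spike exactly on a boundary
#' belongs to the later bin. A bin is 1 when the neuron has at least one spike
#' in it (binary occupancy, not a count: downstream modelling is binary).
#'
#' @param spikes a \code{\link{spike_train_set}}.
#' @param bin_ms bin width in ms (default 20, a width that works well for
#'   motor-cortex population activity).
#' @return An \code{\link{event_matrix}} with \code{ceiling(duration/bin_ms)}
#'   columns and \code{frame_ms = bin_ms}.
#' @examples
#' s <- spike_train_set(list(a = c(5, 25, 27)), duration_ms = 60)
#' unclass(bin_spikes(s, 20))   # [1, 1, 0]
#' @export
bin_spikes <- function(spikes, bin_ms = 20) {
  stopifnot(inherits(spikes, "spike_train_set"))
  if (!is.numeric(bin_ms) || length(bin_ms) != 1L || bin_ms <= 0)
    stop("bin_ms must be a single positive number")
  if (length(spikes$times) < 1L) stop("spike train set has no neurons")
  nbin <- as.integer(ceiling(spikes$duration_ms / bin_ms))
  if (nbin < 2L)
    stop("binning yields fewer than 2 frames; use a smaller bin width")
  m <- t(vapply(spikes$times, function(tt) {
    row <- integer(nbin)
    if (length(tt)) row[unique(floor(tt / bin_ms)) + 1L] <- 1L
    row
  }, integer(nbin)))
  event_matrix(m, neuron_ids = names(spikes$times), frame_ms = bin_ms)
}

#' Drop low-firing-rate neurons
#'
#' Keeps neurons whose overall firing rate (spike count / recording duration)
#' is at least \code{min_rate_hz}; neurons strictly below the cutoff are
#' excluded. Low-rate neurons have too few active states to support inference
#' of transition structure.
#'
#' @param spikes a \code{\link{spike_train_set}}.
#' @param min_rate_hz minimum firing rate in spikes per second (default 5).
#' @return A \code{\link{spike_train_set}} with the surviving neurons, original
#'   order and ids preserved. May contain zero neurons.
#' @export
filter_low_rate <- function(spikes, min_rate_hz = 5) {
  stopifnot(inherits(spikes, "spike_train_set"))
  if (!is.numeric(min_rate_hz) || length(min_rate_hz) != 1L || min_rate_hz < 0)
    stop("min_rate_hz must be a single non-negative number")
  rate <- lengths(spikes$times) / (spikes$duration_ms / 1000)
  keep <- rate >= min_rate_hz
  out <- spikes
  out$times <- spikes$times[keep]
  out
}
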