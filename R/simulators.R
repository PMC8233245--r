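#' Random ground-truth dynamic Bayesian network
#'
#' Samples the structure and parameters of a two-slice temporal network over K
#' binary cluster-state variables. Each node i receives a uniformly sampled
#' parent set (from the slice-t variables, self excluded by default) of size
#' drawn from \code{parents_range}, and additive transition parameters: the
#' activation probability of node i at t + 1 is
#' \deqn{p = clip(b_i + \sum_{j \in \pi_i} a_{j \to i} y_j, \epsilon, 1-\epsilon)}
#' where \eqn{y_j} is the state of parent j at time t. The defaults
#' (base 0.10, gain 0.39, clip at 0.02/0.98) give the canonical two-active-
#' parents transition probability 0.10 + 2 x 0.39 = 0.88.
#'
#' @param K number of nodes (clusters).
#' @param parents_range integer vector \code{c(min, max)} of parent-set sizes
#'   (default \code{c(1, 3)}); \code{c(0, 0)} gives an empty graph with all
#'   transitions at base rate.
#' @param base per-node baseline activation probability (default 0.10).
#' @param gain per-parent additive activation gain (default 0.39).
#' @param p0 initial-slice activation probability (default 0.2).
#' @param clip two probabilities bounding the transition table
#'   (default \code{c(0.02, 0.98)}).
#' @param allow_self if TRUE a node may draw itself as a parent
#'   (default FALSE).
#' @param seed optional RNG seed; identical seeds reproduce the structure.
#' @return A list of class \code{"ground_truth_dbn"} with elements \code{K},
#'   \code{parents} (list of integer parent sets), \code{base}, \code{gain}
#'   (list of per-parent gains aligned with \code{parents}), \code{p0},
#'   \code{clip}.
#' @export
random_ground_truth <- function(K, parents_range = c(1, 3), base = 0.10,
                                gain = 0.39, p0 = 0.2,
                                clip = c(0.02, 0.98), allow_self = FALSE,
                                seed = NULL) {
  K <- as.integer(K)
  if (K < 1L) stop("K must be >= 1")
  parents_range <- as.integer(parents_range)
  pool_size <- if (allow_self) K else K - 1L
  if (max(parents_range) > pool_size)
    stop("parent count ", max(parents_range),
         " infeasible with K=", K, " (pool size ", pool_size, ")")
  if (min(parents_range) < 0L) stop("parent counts must be >= 0")
  # degenerate bounds (0 or 1) are allowed: deterministic tables are valid
  stopifnot(length(clip) == 2L, clip[1L] >= 0, clip[2L] <= 1,
            clip[1L] <= clip[2L])
  if (!is.null(seed)) set.seed(seed)
  base <- rep_len(base, K)
  p0 <- rep_len(p0, K)
  parents <- vector("list", K)
  gains <- vector("list", K)
  for (i in seq_len(K)) {
    np <- if (parents_range[1L] == parents_range[2L]) parents_range[1L]
          else sample(seq(parents_range[1L], parents_range[2L]), 1L)
    pool <- if (allow_self) seq_len(K) else setdiff(seq_len(K), i)
    parents[[i]] <- if (np > 0L) sort(sample(pool, np)) else integer(0)
    gains[[i]] <- rep_len(gain, np)
  }
  structure(list(K = K, parents = parents, base = base, gain = gains,
                 p0 = p0, clip = as.numeric(clip)),
            class = "ground_truth_dbn")
}

#' @export
print.ground_truth_dbn <- function(x, ...) {
  cat("Ground-truth 2TBN:", x$K, "nodes,",
      sum(lengths(x$parents)), "edges (slice t -> t+1)\n")
  for (i in seq_len(x$K))
    cat(sprintf("  node %d <- {%s}  base %.2f\n", i,
                paste(x$parents[[i]], collapse = ","), x$base[i]))
  invisible(x)
}

#' Transition probability of one node given a parent state vector
#'
#' @param dbn a \code{\link{random_ground_truth}} network.
#' @param i node index.
#' @param y full length-K 0/1 state vector at time t.
#' @return The clipped additive activation probability of node i at t + 1.
#' @export
transition_prob <- function(dbn, i, y) {
  stopifnot(inherits(dbn, "ground_truth_dbn"))
  p <- dbn$base[i] + sum(dbn$gain[[i]] * y[dbn$parents[[i]]])
  min(max(p, dbn$clip[1L]), dbn$clip[2L])
}

#' Binary adjacency of a ground-truth network
#'
#' @param dbn a \code{\link{random_ground_truth}} network.
#' @return K x K binary matrix with entry \code{(j, i) = 1} when j is a
#'   parent of i (link j at t -> i at t + 1), node order matching
#'   \code{\link{sample_dbn}} state rows.
#' @export
dbn_adjacency <- function(dbn) {
  stopifnot(inherits(dbn, "ground_truth_dbn"))
  A <- matrix(0L, dbn$K, dbn$K,
              dimnames = list(paste0("c", seq_len(dbn$K)),
                              paste0("c", seq_len(dbn$K))))
  for (i in seq_len(dbn$K)) A[dbn$parents[[i]], i] <- 1L
  A
}

#' Sample cluster-state trajectories from a ground-truth network
#'
#' The initial slice is independent Bernoulli(\code{p0}); each later slice
#' draws node i from Bernoulli of its additive transition probability given
#' the previous slice. Fully seeded and reproducible.
#'
#' @param dbn a \code{\link{random_ground_truth}} network.
#' @param T_len number of time points (>= 2).
#' @param seed optional RNG seed.
#' @return A K x \code{T_len} binary integer cluster-state matrix.
#' @export
sample_dbn <- function(dbn, T_len, seed = NULL) {
  stopifnot(inherits(dbn, "ground_truth_dbn"))
  T_len <- as.integer(T_len)
  if (T_len < 2L) stop("T_len must be >= 2")
  if (!is.null(seed)) set.seed(seed)
  K <- dbn$K
  Y <- matrix(0L, K, T_len,
              dimnames = list(paste0("c", seq_len(K)), NULL))
  Y[, 1L] <- stats::rbinom(K, 1L, dbn$p0)
  lo <- dbn$clip[1L]; hi <- dbn$clip[2L]
  for (t in seq_len(T_len - 1L)) {
    y <- Y[, t]
    p <- vapply(seq_len(K), function(i)
      dbn$base[i] + sum(dbn$gain[[i]] * y[dbn$parents[[i]]]), numeric(1L))
    p <- pmin(pmax(p, lo), hi)
    Y[, t + 1L] <- as.integer(stats::runif(K) < p)
  }
  Y
}

#' Generate flip-noise neurons from cluster-state trajectories
#'
#' Each cluster contributes \code{neurons_per_cluster} neurons; a neuron in
#' cluster i copies the cluster trajectory and flips each frame independently
#' with probability \code{lambda}. \code{lambda} is the noise level and
#' \code{1 - lambda} the within-cluster homogeneity; the expected Hamming
#' distance between two neurons of the same cluster is
#' \code{2 lambda (1 - lambda) T}.
#'
#' @param Y K x T binary cluster-state matrix.
#' @param neurons_per_cluster neurons per cluster (default 10).
#' @param lambda per-frame flip probability in \code{[0, 1]} (default 0.2).
#' @param seed optional RNG seed.
#' @return A list with \code{events} (an \code{\link{event_matrix}} of
#'   P = K * neurons_per_cluster rows) and \code{partition} (the ground-truth
#'   integer membership vector, named like the event rows).
#' @export
generate_neurons <- function(Y, neurons_per_cluster = 10, lambda = 0.2,
                             seed = NULL) {
  Y <- check_state_matrix(Y)
  m <- as.integer(neurons_per_cluster)
  if (m < 1L) stop("neurons_per_cluster must be >= 1")
  if (!is.numeric(lambda) || lambda < 0 || lambda > 1)
    stop("lambda must lie in [0, 1]")
  if (!is.null(seed)) set.seed(seed)
  K <- nrow(Y); T_ <- ncol(Y)
  part <- rep(seq_len(K), each = m)
  base <- Y[part, , drop = FALSE]
  flips <- matrix(stats::runif(length(base)) < lambda, nrow(base), T_)
  vals <- ifelse(flips, 1L - base, base)
  ids <- paste0("n", seq_len(K * m))
  names(part) <- ids
  attr(part, "K") <- K
  list(events = event_matrix(vals, neuron_ids = ids),
       partition = part)
}

#' Mean pairwise Hamming distance between cluster-state rows
#'
#' The cluster-similarity summary used to grade how challenging a simulated
#' dataset is: the average, over all unordered cluster pairs, of the Hamming
#' distance between their state trajectories. Lower values mean more similar
#' (harder to separate) clusters.
#'
#' @param Y K x T binary cluster-state matrix, K >= 2.
#' @return A single non-negative number.
#' @export
cluster_similarity <- function(Y) {
  Y <- check_state_matrix(Y)
  if (nrow(Y) < 2L) stop("need at least 2 clusters")
  D <- stats::dist(Y, method = "manhattan")
  mean(D)
}

#' Configuration for the integrate-and-fire microcircuit simulator
#'
#' Four wired neuron groups A, B, C, D (defaults 40 neurons each) of leaky
#' integrate-and-fire neurons with additive Gaussian membrane noise. Group A
#' receives a shared stochastic stimulus; each B and C neuron has 2-3 parents
#' in A; each D neuron has 2-3 parents in B and 2-3 in C. A presynaptic spike
#' increments the target membrane potential by the class-specific synaptic
#' weight after \code{delay_ms}.
#'
#' Membrane dynamics per Euler step:
#' \code{V <- V + dt (V_rest - V) / tau + sigma tau (-0.5) eps},
#' with \code{eps ~ N(0, 1)} drawn per step and neuron. The noise term is
#' applied literally per step by default (its sign is immaterial by symmetry
#' of \code{eps}); set \code{noise_scaling = "sqrt_dt"} for diffusion scaling
#' by \code{sqrt(dt)}.
#'
#' Stimulus model: stimulus events arrive as a Bernoulli process in time at
#' \code{stim_rate_hz}; each event is a brief burst of
#' \code{volleys_per_event} input volleys spaced \code{volley_interval_ms}
#' apart, with a shared event strength \code{q ~ U(0, 1)}. Every volley
#' recruits each group-A neuron independently with probability \code{q}
#' (a graded population stimulus); recruited neurons receive \code{w_stim}.
#' The volley repetition makes each downstream neuron's response a sharp,
#' nearly deterministic function of the shared strength q, so neurons of one
#' group produce near-identical event trajectories while groups with
#' different effective thresholds stay distinguishable.
#'
#' Synaptic weights: \code{w_ab} is singly suprathreshold (any one A parent
#' drives a B neuron) while \code{w_ac} needs two coincident A parents; this
#' difference in effective threshold is what distinguishes the B and C
#' responses. \code{w_bd}/\code{w_cd} require about three coincident parents.
#'
#' @param group_sizes integer vector of the four group sizes
#'   (default \code{c(40, 40, 40, 40)}).
#' @param tau_ms membrane time constant (default 20).
#' @param v_rest_mv rest potential (default -70).
#' @param v_thresh_mv firing threshold (default -54); a neuron fires when V
#'   strictly exceeds it, then resets.
#' @param v_reset_mv reset potential (default \code{v_rest_mv}).
#' @param refractory_ms absolute refractory period (default 5).
#' @param sigma noise scale of the membrane equation (default 0.1).
#' @param w_stim stimulus increment to recruited A neurons (default 20).
#' @param w_ab,w_ac,w_bd,w_cd synaptic increments per connection class
#'   (defaults 17, 9, 6, 6 mV).
#' @param parents_range parents per target drawn uniformly from this range
#'   (default \code{c(2, 3)}), independently for the B<-A, C<-A, D<-B and
#'   D<-C fan-ins.
#' @param stim_rate_hz stimulus event rate (default 10).
#' @param volleys_per_event input volleys per stimulus event (default 3).
#' @param volley_interval_ms spacing between volleys (default 6, just above
#'   the refractory period so a neuron can follow every volley).
#' @param delay_ms synaptic/stimulus-to-response transmission delay
#'   (default 20, one analysis frame at the default 20 ms binning).
#' @param dt_ms Euler step (default 1).
#' @param duration_ms total simulated time (default 60000).
#' @param noise_scaling \code{"literal"} (default) or \code{"sqrt_dt"}.
#' @return A list of class \code{"if_network_config"}.
#' @export
if_network_config <- function(group_sizes = c(40, 40, 40, 40),
                              tau_ms = 20, v_rest_mv = -70,
                              v_thresh_mv = -54, v_reset_mv = v_rest_mv,
                              refractory_ms = 5, sigma = 0.1,
                              w_stim = 20, w_ab = 17, w_ac = 9,
                              w_bd = 6, w_cd = 6,
                              parents_range = c(2, 3),
                              stim_rate_hz = 10, volleys_per_event = 3,
                              volley_interval_ms = 6, delay_ms = 20,
                              dt_ms = 1, duration_ms = 60000,
                              noise_scaling = c("literal", "sqrt_dt")) {
  noise_scaling <- match.arg(noise_scaling)
  group_sizes <- as.integer(group_sizes)
  if (length(group_sizes) != 4L || any(group_sizes < 1L))
    stop("group_sizes must be four positive integers")
  if (tau_ms <= 0 || dt_ms <= 0 || duration_ms <= 0)
    stop("tau_ms, dt_ms and duration_ms must be positive")
  if (v_thresh_mv <= v_rest_mv)
    stop("v_thresh_mv must exceed v_rest_mv")
  if (refractory_ms < 0 || sigma < 0 || stim_rate_hz < 0 || delay_ms < 0)
    stop("refractory_ms, sigma, stim_rate_hz and delay_ms must be >= 0")
  volleys_per_event <- as.integer(volleys_per_event)
  if (volleys_per_event < 1L || volley_interval_ms < 0)
    stop("volleys_per_event must be >= 1 and volley_interval_ms >= 0")
  parents_range <- as.integer(parents_range)
  if (min(parents_range) < 1L)
    stop("each target needs at least one parent")
  structure(list(group_sizes = group_sizes, tau_ms = tau_ms,
                 v_rest_mv = v_rest_mv, v_thresh_mv = v_thresh_mv,
                 v_reset_mv = v_reset_mv, refractory_ms = refractory_ms,
                 sigma = sigma, w_stim = w_stim, w_ab = w_ab, w_ac = w_ac,
                 w_bd = w_bd, w_cd = w_cd, parents_range = parents_range,
                 stim_rate_hz = stim_rate_hz,
                 volleys_per_event = volleys_per_event,
                 volley_interval_ms = volley_interval_ms, delay_ms = delay_ms,
                 dt_ms = dt_ms, duration_ms = duration_ms,
                 noise_scaling = noise_scaling),
            class = "if_network_config")
}

#' Simulate the noisy integrate-and-fire microcircuit
#'
#' Euler-integrates the membrane equation for the four wired groups (see
#' \code{\link{if_network_config}}), with threshold-crossing spikes, reset,
#' and an absolute refractory period during which no second spike can occur.
#' Ground truth at the group level is the graph A -> B, A -> C, B -> D,
#' C -> D.
#'
#' @param cfg an \code{\link{if_network_config}}.
#' @param seed optional RNG seed; all randomness (wiring, stimulus, noise)
#'   derives from it, so output is reproducible bit for bit.
#' @return A list with \code{spikes} (a \code{\link{spike_train_set}}),
#'   \code{partition} (true group membership 1..4, A..D, named by neuron),
#'   \code{truth} (4 x 4 binary group-level adjacency, rows = source), and
#'   \code{config}.
#' @export
simulate_if_network <- function(cfg = if_network_config(), seed = NULL) {
  stopifnot(inherits(cfg, "if_network_config"))
  if (!is.null(seed)) set.seed(seed)
  gs <- cfg$group_sizes
  n <- sum(gs)
  group <- rep(1:4, times = gs)
  idx <- split(seq_len(n), group)
  names(idx) <- c("A", "B", "C", "D")

  # wiring: per-target parent lists with class-specific weights
  draw_parents <- function(pool) {
    np <- sample(seq(cfg$parents_range[1L], cfg$parents_range[2L]), 1L)
    sample(pool, min(np, length(pool)))
  }
  parents <- vector("list", n)
  weights <- vector("list", n)
  for (j in idx$B) {
    parents[[j]] <- draw_parents(idx$A)
    weights[[j]] <- rep(cfg$w_ab, length(parents[[j]]))
  }
  for (j in idx$C) {
    parents[[j]] <- draw_parents(idx$A)
    weights[[j]] <- rep(cfg$w_ac, length(parents[[j]]))
  }
  for (j in idx$D) {
    pb <- draw_parents(idx$B)
    pc <- draw_parents(idx$C)
    parents[[j]] <- c(pb, pc)
    weights[[j]] <- c(rep(cfg$w_bd, length(pb)), rep(cfg$w_cd, length(pc)))
  }

  dt <- cfg$dt_ms
  n_steps <- as.integer(ceiling(cfg$duration_ms / dt))
  delay_steps <- max(1L, as.integer(round(cfg$delay_ms / dt)))
  refr_steps <- as.integer(ceiling(cfg$refractory_ms / dt))
  volley_off <- as.integer(round(cfg$volley_interval_ms / dt)) *
    (seq_len(cfg$volleys_per_event) - 1L)
  noise_mult <- cfg$sigma * cfg$tau_ms * 0.5 *
    if (cfg$noise_scaling == "sqrt_dt") sqrt(dt) else 1
  leak <- dt / cfg$tau_ms
  p_event <- min(1, cfg$stim_rate_hz * dt / 1000)

  V <- rep(cfg$v_rest_mv, n)
  refr_until <- integer(n)              # step until which a neuron is silent
  # ring buffer of pending synaptic/stimulus input per future step
  horizon <- max(delay_steps, max(volley_off)) + 1L
  pending <- matrix(0, horizon, n)
  spikes <- vector("list", n)
  nA <- length(idx$A)

  for (s in seq_len(n_steps)) {
    slot <- (s %% horizon) + 1L
    inp <- pending[slot, ]
    pending[slot, ] <- 0

    # shared graded stimulus to group A: a burst of volleys, recruitment
    # resampled per volley at the event's shared strength q
    if (p_event > 0 && stats::runif(1) < p_event) {
      q <- stats::runif(1)
      for (off in volley_off) {
        hit <- idx$A[stats::runif(nA) < q]
        if (!length(hit)) next
        if (off == 0L) {
          inp[hit] <- inp[hit] + cfg$w_stim
        } else {
          vs <- ((s + off) %% horizon) + 1L
          pending[vs, hit] <- pending[vs, hit] + cfg$w_stim
        }
      }
    }

    eps <- stats::rnorm(n)
    V <- V + leak * (cfg$v_rest_mv - V) + noise_mult * eps + inp
    active <- s >= refr_until
    V[!active] <- cfg$v_reset_mv
    fired <- active & (V > cfg$v_thresh_mv)
    if (any(fired)) {
      w <- which(fired)
      for (j in w) spikes[[j]] <- c(spikes[[j]], (s - 1L) * dt)
      V[w] <- cfg$v_reset_mv
      refr_until[w] <- s + refr_steps
      # schedule synaptic delivery delay_steps ahead
      tgt_slot <- ((s + delay_steps) %% horizon) + 1L
      for (j in seq_len(n)) {
        if (length(parents[[j]])) {
          hitw <- weights[[j]][parents[[j]] %in% w]
          if (length(hitw))
            pending[tgt_slot, j] <- pending[tgt_slot, j] + sum(hitw)
        }
      }
    }
  }

  ids <- paste0(rep(c("A", "B", "C", "D"), times = gs),
                unlist(lapply(gs, seq_len)))
  names(spikes) <- ids
  part <- group
  names(part) <- ids
  attr(part, "K") <- 4L
  truth <- matrix(0L, 4L, 4L, dimnames = list(c("A", "B", "C", "D"),
                                              c("A", "B", "C", "D")))
  truth["A", "B"] <- truth["A", "C"] <- truth["B", "D"] <- truth["C", "D"] <- 1L
  list(spikes = spike_train_set(spikes, cfg$duration_ms),
       partition = part, truth = truth, config = cfg)
}
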