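---
title: "Methods: causal inference for microcircuits from binary neural events"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: causal inference for microcircuits from binary neural events}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem and the model

Calcium imaging and multi-electrode electrophysiology record the activity of
dozens to hundreds of neurons simultaneously. After standard preprocessing,
such a recording is a binary P × T event matrix **s**: entry (i, t) = 1 when
neuron i emitted a spike or a calcium transient in frame t. The scientific
question this package addresses is *causal*: which neural populations drive
which, at the time scale of one frame?

Applying causal discovery directly to hundreds of neuron-level series is
statistically fragile: neurons come in functional ensembles whose members
carry near-duplicate information, and models fitted at single-neuron
resolution overfit and destabilize. The package therefore works at the
mesoscopic (microcircuit) scale in three stages:

1. **Neuron clustering.** Neurons are grouped into K ensembles by the
   similarity of their binary trajectories (zero-lag synchrony). A k-nearest-
   neighbour graph over neurons is built with the Hamming distance between
   trajectory rows; communities are found with the walktrap algorithm, and
   the dendrogram is cut at the level of maximal modularity — K is decided by
   the data, never supplied by the user.
2. **Cluster states.** Each cluster A gets a binary latent state series
   Y^A(t), inferred by voting: Y^A(t) = 1 when the fraction of cluster-A
   neurons active at t strictly exceeds a threshold (0.5 by default —
   majority voting). A P × K loading matrix of relative mutual information
   between each neuron and each cluster state summarizes how cleanly the
   partition explains single-neuron activity.
3. **Transition network.** Interactions among cluster states are modelled as
   a two-slice temporal Bayesian network: a first-order, time-invariant
   Markov model of P(**Y**(t+1) | **Y**(t)). For each target cluster a, a
   random-forest regression predicts Y^a(t+1) from the full state vector
   **Y**(t) (bootstrap per tree, random predictor subset per split), and the
   variance-reduction importance of predictor b becomes the weight of the
   directed link b → a. Tree ensembles capture nonlinear and combinational
   effects (e.g. "B activates only when A and C were both active") that
   pairwise measures miss. Self-links are legitimate candidates — persistent
   ensembles drive themselves.

The fitting entry point is `caim()`, which returns a classed object carrying
the partition, the state matrix, the loading matrix and the K × K weight
matrix, with the usual `print`/`summary`/`coef`/`plot` methods.

## Parameters that matter

* `k_neighbors` — neighbours per neuron in the k-NN graph. This sets the
  resolution of the community search and should be commensurate with the
  smallest real ensemble: if k is far below the ensemble size the graph
  inside a large ensemble is sparse enough that walktrap fractures it; if k
  reaches past the ensemble size, every neuron is forced to adopt neighbours
  from the next-most-similar ensemble and the closest pair of ensembles
  merges. Because ensemble sizes are unknown a priori, the default scans a
  grid (3–64 densely, then doubling) in increasing order and accepts the
  first partition that is *stable* — reproduced exactly at the next
  neighbour count. Stability, not silhouette, is the primary criterion:
  silhouette systematically prefers merging a close pair of ensembles
  whenever the next ensemble is much farther away, whereas spurious
  fragmentations of a homogeneous ensemble are never reproducible across
  adjacent k. If no stable plateau exists the best-silhouette candidate is
  used as a fallback.
* `walk_steps` — walktrap random-walk length, default 4 (the algorithm's
  canonical default). Short walks resolve small communities.
* `threshold` — the voting threshold in [0, 1], default 0.5. The comparison
  is strict (`>`), so a 10-neuron cluster needs 6 active members to be "on"
  at 0.5. Higher thresholds sparsify cluster activation; edge recovery is
  robust across a broad band (0.3–0.7 in the validation suite).
* `n_trees` (default 1000) and `mtry` (default ⌈√K⌉) — the forest size and
  per-split predictor subset, following the established defaults of
  tree-ensemble network inference. Importances per target are normalized to
  sum to one, which makes weights comparable across targets; the printed
  weights of a target's two drivers then read directly as shares of
  explained transition structure. A constant (silent or saturated) target
  has no variance to attribute and yields an all-zero column with a warning
  rather than an error.
* Relative mutual information normalization: the plug-in mutual information
  of two binary series is divided by `min(H(X), H(Y))` (option
  `rmi_normalize`, alternatives `"max"` and `"hy"`). Min-entropy
  normalization guarantees the [0, 1] range, equals 1 for identical or
  complementary non-constant series, and is 0 by convention when either
  series is constant. The literature contains several conventions; this one
  is the least surprising for the loading-matrix use case and is exposed as
  an option rather than hard-coded.

## Data handling conventions

Spike trains are binned into non-overlapping half-open windows
[(b−1)w, bw) — a spike exactly on a boundary belongs to the later bin — and
a bin records occupancy (0/1), not a count, because the model is binary.
The default width of 20 ms suits motor-cortex population activity. Neurons
firing below 5 spikes/s are excluded by default before causal analysis
(strictly below the cutoff is dropped): such neurons have too few active
frames to support transition estimates. Event matrices, partitions, state
matrices and edge lists all have plain delimited-text readers and writers,
and `run_pipeline()` stages its outputs in a temporary directory, moving
them into place only on success.

## The simulators

Validation never depends on external data: two generators produce datasets
with known ground truth.

**Transition-network simulator.** `random_ground_truth(K)` draws, for each
node, a parent set of size 1–3 (uniformly, self excluded by default) and
additive transition parameters: activation probability
p = clip(b + Σ a·y_parent, 0.02, 0.98) with base b = 0.10 and per-parent
gain a = 0.39, so two active parents give the canonical 0.88. The first
slice is independent Bernoulli(0.2) — with T = 5000 the influence of the
arbitrary initial slice is negligible, so no burn-in is discarded.
`sample_dbn()` simulates the chain; `generate_neurons()` expands each
cluster trajectory into neurons by flipping each frame independently with
probability λ (the noise level; 1 − λ is within-cluster homogeneity). The
expected Hamming distance between same-cluster neurons is 2λ(1−λ)T, a
closed form the test suite checks by Monte Carlo. `cluster_similarity()`
reports the average pairwise Hamming distance between cluster state rows,
the difficulty measure used when comparing scenarios.

**Integrate-and-fire microcircuit.** 160 leaky integrate-and-fire neurons in
four groups A–D of 40, wired A→B, A→C (each B/C neuron has 2–3 parents in
A) and B,C→D (each D neuron has 2–3 parents in each of B and C). Membrane
dynamics follow the forward-Euler step

V ← V + dt·(V_rest − V)/τ + σ·τ·(−0.5)·ε,   ε ~ N(0, 1) per step and neuron,

with τ = 20 ms, V_rest = −70 mV, threshold −54 mV (strict crossing), reset
to rest, and a 5 ms absolute refractory period. The noise term is applied
literally per step by default; a √dt diffusion scaling is available as
`noise_scaling = "sqrt_dt"` (at the default dt = 1 ms the two coincide, and
the sign of the noise term is immaterial by symmetry of ε). A presynaptic
spike increments each child's potential by a class-specific weight after a
transmission delay.

Several quantities the model description leaves open had to be fixed; they
are config fields, chosen once on physical grounds:

* *Stimulus.* Group A receives a shared stochastic stimulus: events arrive
  as a Bernoulli process at 10 Hz, and each event is a burst of three input
  volleys 6 ms apart (just above the refractory period). Each event carries
  a shared strength q ~ U(0, 1), and every volley recruits each A neuron
  independently with probability q. The shared q makes the four groups
  respond as populations; the volley repetition sharpens each neuron's
  event response towards a deterministic function of q, which is what makes
  the groups internally homogeneous and hence recoverable by clustering.
* *Weights.* w_stim = 20 mV (suprathreshold), w_AB = 17 mV — singly
  suprathreshold, so any one recruited parent drives a B neuron — while
  w_AC = 9 mV needs two coincident parent spikes, and w_BD = w_CD = 6 mV
  need about three. The wiring description only requires the A→B and A→C
  weights to differ; giving them different *effective activation
  thresholds* (any-parent vs. two-parents vs. three-parents) is the design
  choice that makes B, C and D respond to distinguishably different ranges
  of the stimulus strength, so that the groups neither merge nor shadow one
  another.
* *Transmission delay* = 20 ms, equal to one analysis frame at the default
  binning. Influence between groups is thereby expressed at the one-step
  lag that the two-slice transition model estimates. A shorter delay mixes
  cause and effect within a single frame, where a first-order model cannot
  see it; this is a property of the analysis time scale, not of the
  inference algorithm.
* *Noise scale* σ = 0.1: the stationary membrane fluctuation is then about
  4 standard deviations below threshold, so spontaneous spikes are rare but
  the noise still perturbs near-threshold responses.

With these defaults the simulation reproduces the qualitative regime the
model targets: clustering recovers the four groups nearly perfectly, the
four wired group-level links carry dominant, bimodally separated weights
(the two A links strongest, the B→D/C→D pair sharing the D column roughly
equally), and the stimulus-driven group A — which has no parents — spreads
its column mass mostly onto its own persistence link.

## Evaluation conventions

* **Rand index**: plain (unadjusted) fraction of object pairs on which two
  partitions agree; 1 means identical up to label renaming.
* **Silhouette**: standard (b − a)/max(a, b) averaged over neurons, with the
  same Hamming trajectory metric as the clustering for internal consistency;
  singleton clusters and degenerate a = b = 0 score 0.
* **Edge-recovery AUC**: rank-based (Mann–Whitney) probability that a random
  true link outweighs a random non-link, midrank ties counting one half —
  threshold-free and invariant to monotone weight transforms. Self-links
  are excluded from the positive/negative sets whenever the ground truth
  places no self-links (the generators here do not), and included
  otherwise; a flag overrides. The AUC pools all ordered node pairs into a
  single ROC rather than averaging per-target curves.
* Comparing a detected partition's network against a ground-truth graph
  requires aligning node orders; `match_partition_labels()` maps each
  detected cluster to the reference group with the largest member overlap.

## Numerical and degenerate-input choices

Distance ties in the neighbour search break deterministically towards the
lower neuron index; exact search is the default (approximate subsampled
search is opt-in) so clustering is reproducible bit for bit. Disconnected
neighbour graphs are partitioned per connected component; an edgeless graph
falls back to singletons with a warning. All-zero or all-one neurons are
valid input — their mutual distance 0 groups them. Plug-in mutual
information is clamped to [0, denominator] against floating-point
excursions. Every stochastic stage takes a seed, and a single pipeline seed
is expanded deterministically into per-stage seeds, so identical
config + seed reproduces byte-identical artifacts.

## What the tests do and do not show

The validation suite runs at the study scale the generators define:
6 or 9 clusters × 10 neurons × 5000 frames for the transition-network
simulations (noise levels 0.1–0.3), and the default 60 s microcircuit. At
that scale the suite asserts exact recovery (detected K, Rand index 1,
edge AUC 1 across voting thresholds 0.3–0.7) — comfortable margins, not
knife-edge outcomes. These checks validate the machinery, not the
difficulty of any particular real recording: the flip-noise generator makes
within-cluster deviations independent across neurons and frames, which is
kinder than biological noise (no bursting, no rate drift, no overlapping
membership), and the microcircuit's groups respond to a single shared
stimulus dimension. Real data will show lower loadings, less clear-cut
partitions and graded edge weights.

## Known limitations

Causal sufficiency is assumed: an unrecorded ensemble that drives two
recorded ones will induce a spurious link between them. The transition
structure is assumed time-invariant; if the true dependencies drift, the
learned graph is an average. The network output is a *ranking* of candidate
links — the median-weight rule (`strong_links()`) is a display heuristic,
not a calibrated significance threshold: strictly more than half of K²
distinct weights always fall below the median, so the strong set has close
to K²/2 members whatever the data. Hard edge selection with error control
is out of scope. Finally, clustering assumes each neuron belongs to exactly
one ensemble; soft or overlapping membership is not modelled.
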