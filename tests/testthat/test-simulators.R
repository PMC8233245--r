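test_that("ground-truth generation is seeded and respects parent ranges", {
  d1 <- random_ground_truth(6, seed = 42)
  d2 <- random_ground_truth(6, seed = 42)
  expect_identical(d1, d2)
  expect_true(all(lengths(d1$parents) >= 1 & lengths(d1$parents) <= 3))
  # no self parents by default
  for (i in 1:6) expect_false(i %in% d1$parents[[i]])
  # empty parent range: transitions at base rate
  d0 <- random_ground_truth(4, parents_range = c(0, 0), seed = 1)
  expect_true(all(lengths(d0$parents) == 0))
  expect_error(random_ground_truth(3, parents_range = c(1, 3)),
               "infeasible")
})

test_that("additive transition tables give the canonical two-parent case", {
  dbn <- random_ground_truth(4, parents_range = c(2, 2), seed = 1)
  i <- 1L
  y <- integer(4)
  expect_equal(transition_prob(dbn, i, y), 0.10)
  y[dbn$parents[[i]]] <- 1L
  expect_equal(transition_prob(dbn, i, y), 0.88)   # 0.10 + 2 x 0.39
  # clipping keeps probabilities valid
  dbn$gain[[i]] <- c(0.5, 0.5)
  expect_equal(transition_prob(dbn, i, y), 0.98)
})

test_that("dbn sampling follows its transition tables", {
  # forced activation from the second slice on
  dbn <- random_ground_truth(3, parents_range = c(0, 0), base = 1,
                             clip = c(0.001, 1), p0 = 0, seed = 2)
  Y <- sample_dbn(dbn, 50, seed = 3)
  expect_true(all(Y[, -1] == 1L))
  expect_true(all(Y[, 1] == 0L))
  # parentless node at base 0.5: empirical mean within 3 sigma
  dbn2 <- random_ground_truth(2, parents_range = c(0, 0), base = 0.5,
                              seed = 4)
  Y2 <- sample_dbn(dbn2, 1e5, seed = 5)
  expect_lt(abs(mean(Y2[1, -1]) - 0.5), 3 * sqrt(0.25 / (1e5 - 1)))
  # deterministic copy chain: exact lagged copies
  chain <- copy_chain_dbn(4)
  Yc <- sample_dbn(chain, 200, seed = 6)
  for (i in 2:4)
    expect_identical(unname(Yc[i, -1]), unname(Yc[i - 1, -200]))
  # seeded reproducibility
  expect_identical(sample_dbn(dbn2, 100, seed = 7),
                   sample_dbn(dbn2, 100, seed = 7))
})

test_that("flip-noise neurons have the closed-form expected Hamming gap", {
  dbn <- random_ground_truth(6, seed = 10)
  Y <- sample_dbn(dbn, 5000, seed = 11)
  gen <- generate_neurons(Y, neurons_per_cluster = 10, lambda = 0.2,
                          seed = 12)
  expect_identical(dim(unclass(gen$events)), c(60L, 5000L))
  expect_identical(as.vector(table(gen$partition)), rep(10L, 6))
  # lambda = 0 copies the cluster trajectory exactly
  gen0 <- generate_neurons(Y, neurons_per_cluster = 2, lambda = 0, seed = 1)
  expect_identical(unname(unclass(gen0$events)[1, ]), unname(Y[1, ]))
  # E[Hamming] = 2 lambda (1 - lambda) T between same-cluster neurons
  lam <- 0.2; T_len <- 5000
  v <- unclass(gen$events)
  d_within <- sapply(seq(1, 51, by = 10), function(i)
    sum(v[i, ] != v[i + 1, ]))
  expected <- 2 * lam * (1 - lam) * T_len
  sd_one <- sqrt(T_len * 0.32 * (1 - 0.32))
  expect_lt(abs(mean(d_within) - expected), 3 * sd_one / sqrt(6))
  # empirical flip rate approaches lambda
  flips <- mean(v != Y[gen$partition, ])
  expect_lt(abs(flips - lam), 0.01)
})

test_that("cluster similarity is the mean pairwise Hamming distance", {
  Y <- rbind(a = c(0L, 0L, 1L, 1L), b = c(0L, 1L, 1L, 0L))
  expect_equal(cluster_similarity(Y), 2)
  expect_equal(cluster_similarity(rbind(Y[1, ], Y[1, ])), 0)
  comp <- rbind(rep(0L, 10), rep(1L, 10))
  expect_equal(cluster_similarity(comp), 10)
  expect_error(cluster_similarity(Y[1, , drop = FALSE]), "at least 2")
})

test_that("membrane equation is at rest without noise or stimulus", {
  cfg <- if_network_config(sigma = 0, stim_rate_hz = 0, duration_ms = 2000,
                           group_sizes = c(5, 5, 5, 5))
  res <- simulate_if_network(cfg, seed = 1)
  expect_identical(sum(lengths(res$spikes$times)), 0L)
})

test_that("a suprathreshold input spike fires the target after the delay", {
  # one-step synaptic delay; drive A hard so every A neuron fires, then
  # check B neurons (singly suprathreshold w_ab) fire one step later
  cfg <- if_network_config(sigma = 0, stim_rate_hz = 1000, delay_ms = 1,
                           volleys_per_event = 1, duration_ms = 40,
                           group_sizes = c(4, 4, 4, 4))
  set.seed(2)
  res <- simulate_if_network(cfg, seed = 8)
  tA <- res$spikes$times[res$partition == 1]
  tB <- res$spikes$times[res$partition == 2]
  expect_gt(min(lengths(tA)), 0)
  # every B spike is exactly 1 ms after some A spike
  allA <- sort(unique(unlist(tA)))
  for (tt in unlist(tB)) expect_true((tt - 1) %in% allA)
})

test_that("the refractory period is never violated", {
  res <- simulate_if_network(if_network_config(duration_ms = 10000),
                             seed = 33)
  isi <- unlist(lapply(res$spikes$times, diff))
  expect_gte(min(isi), res$config$refractory_ms)
})

test_that("the microcircuit simulator is bit-reproducible given a seed", {
  cfg <- if_network_config(duration_ms = 3000, group_sizes = c(8, 8, 8, 8))
  r1 <- simulate_if_network(cfg, seed = 5)
  r2 <- simulate_if_network(cfg, seed = 5)
  expect_identical(r1$spikes, r2$spikes)
  expect_identical(r1$truth, r2$truth)
})

test_that("the group-level truth graph is the planted wiring", {
  res <- simulate_if_network(if_network_config(duration_ms = 2000,
                                               group_sizes = c(3, 3, 3, 3)),
                             seed = 2)
  expect_identical(sum(res$truth), 4L)
  expect_identical(res$truth["A", "B"] + res$truth["A", "C"] +
                     res$truth["B", "D"] + res$truth["C", "D"], 4L)
})
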