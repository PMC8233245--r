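test_that("voting threshold is a strict inequality", {
  # one cluster of 10 neurons: 6 active, then exactly 5, then 0
  E <- event_matrix(cbind(c(rep(1, 6), rep(0, 4)),
                          c(rep(1, 5), rep(0, 5)),
                          rep(0, 10)))
  part <- rep(1L, 10)
  Y <- infer_cluster_states(E, part, 0.5)
  expect_identical(unname(Y[1, ]), c(1L, 0L, 0L))
  # threshold 0 marks any active frame; threshold 1 marks none
  expect_identical(unname(infer_cluster_states(E, part, 0)[1, ]),
                   c(1L, 1L, 0L))
  expect_identical(unname(infer_cluster_states(E, part, 1)[1, ]),
                   c(0L, 0L, 0L))
  expect_error(infer_cluster_states(E, part, 1.2), "\\[0, 1\\]")
})

test_that("single-neuron clusters vote as that neuron", {
  E <- event_matrix(rbind(c(1, 0, 1, 1), c(0, 0, 1, 0)))
  Y <- infer_cluster_states(E, c(1L, 2L), 0.5)
  expect_identical(unname(Y), unname(unclass(E)))
})

test_that("relative MI hits its identity, constant and independence cases", {
  set.seed(7)
  x <- rbinom(500, 1, 0.4)
  expect_equal(relative_mutual_information(x, x), 1)
  # complementary series carry the same information
  expect_equal(relative_mutual_information(x, 1L - x), 1)
  expect_equal(relative_mutual_information(x, rep(0L, 500)), 0)
  expect_equal(relative_mutual_information(rep(1L, 500), x), 0)
  # long independent series: plug-in MI bias is O(1/n)
  x <- rbinom(1e5, 1, 0.5)
  y <- rbinom(1e5, 1, 0.5)
  expect_lt(relative_mutual_information(x, y), 0.01)
  expect_error(relative_mutual_information(x, y[-1]), "lengths differ")
})

test_that("relative MI is symmetric, bounded and relabel-invariant", {
  set.seed(19)
  for (i in 1:20) {
    x <- rbinom(200, 1, runif(1, 0.1, 0.9))
    y <- as.integer(xor(x, rbinom(200, 1, runif(1, 0, 0.5))))
    r <- relative_mutual_information(x, y)
    expect_gte(r, 0); expect_lte(r, 1)
    expect_equal(relative_mutual_information(y, x), r)
    expect_equal(relative_mutual_information(1L - x, 1L - y), r)
  }
})

test_that("loading matrix exposes the planted block structure", {
  sim <- simulate_dbn_dataset(3, T_len = 2000, neurons_per_cluster = 5,
                              lambda = 0.2, seed = 21,
                              parents_range = c(1, 2))
  Y <- sim$states
  L <- loading_matrix(sim$events, Y)
  expect_true(all(L >= 0 & L <= 1))
  own <- cbind(seq_along(sim$partition), as.integer(sim$partition))
  mask <- matrix(FALSE, nrow(L), ncol(L)); mask[own] <- TRUE
  expect_gt(mean(L[mask]), mean(L[!mask]))
  # a neuron identical to its cluster state loads 1 on that cluster
  E2 <- event_matrix(rbind(Y[1, ], unclass(sim$events)),
                     neuron_ids = paste0("x", 1:16))
  L2 <- loading_matrix(E2, Y)
  expect_equal(unname(L2[1, 1]), 1)
  # full flip noise destroys the association
  half <- generate_neurons(Y, neurons_per_cluster = 2, lambda = 0.5,
                           seed = 4)
  Lh <- loading_matrix(half$events, Y)
  expect_lt(max(diag(Lh[seq(1, 6, by = 2), ])), 0.02)
})

test_that("within-cluster loading decreases monotonically with noise", {
  means <- vapply(c(0, 0.1, 0.2, 0.3), function(lam) {
    sim <- simulate_dbn_dataset(3, T_len = 2000, neurons_per_cluster = 4,
                                lambda = lam, seed = 77,
                                parents_range = c(1, 2))
    L <- loading_matrix(sim$events, sim$states)
    mean(L[cbind(seq_along(sim$partition), as.integer(sim$partition))])
  }, numeric(1))
  expect_true(all(diff(means) < 0))
})

test_that("state matrices round-trip through labelled text", {
  Y <- rbind(c1 = c(1L, 0L, 1L), c2 = c(0L, 0L, 1L))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_state_matrix(Y, f)
  expect_identical(read_state_matrix(f), Y)
})
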