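test_that("lagged design aligns predictors with next-step responses", {
  Y <- rbind(c1 = c(1L, 0L, 1L, 0L))
  d <- make_lagged_design(Y)
  expect_identical(unname(d$predictors[, 1]), c(1L, 0L, 1L))
  expect_identical(unname(d$responses[, 1]), c(0L, 1L, 0L))
  # constant series stays constant; row count is T - 1
  Yc <- rbind(c1 = rep(1L, 7), c2 = rep(0L, 7))
  dc <- make_lagged_design(Yc)
  expect_identical(nrow(dc$predictors), 6L)
  expect_true(all(dc$predictors[, 1] == 1L))
  expect_error(make_lagged_design(rbind(c(1L))), "at least 2")
})

test_that("a perfect one-step copy owns the importance of its target", {
  set.seed(2)
  x <- rbinom(800, 1, 0.5)
  Y <- rbind(c1 = x, c2 = c(0L, x[-800]))   # c2 copies c1 with lag 1
  d <- make_lagged_design(Y)
  imp <- target_importances(d, "c2", n_trees = 300, seed = 10)
  expect_gt(imp[["c1"]], 0.95)
  expect_lt(imp[["c2"]], 0.05)
  expect_equal(sum(imp), 1)
})

test_that("unpredictable targets get near-uniform importances", {
  set.seed(14)
  K <- 5
  Y <- matrix(rbinom(K * 3000, 1, 0.5), K,
              dimnames = list(paste0("c", 1:K), NULL))
  d <- make_lagged_design(Y)
  imp <- target_importances(d, 1, n_trees = 200, seed = 3)
  expect_lt(max(imp), 3 / K)
  expect_equal(sum(imp), 1)
})

test_that("importances are reproducible under a fixed seed", {
  set.seed(5)
  Y <- matrix(rbinom(4 * 400, 1, 0.4), 4)
  d <- make_lagged_design(Y)
  i1 <- target_importances(d, 2, n_trees = 100, seed = 99)
  i2 <- target_importances(d, 2, n_trees = 100, seed = 99)
  expect_identical(i1, i2)
})

test_that("constant responses yield a zero column with a warning", {
  Y <- rbind(c1 = rep(1L, 50), c2 = rbinom(50, 1, 0.5))
  d <- make_lagged_design(Y)
  expect_warning(imp <- target_importances(d, "c1", n_trees = 50),
                 "constant")
  expect_identical(unname(imp), c(0, 0))
  # the full network still runs, with the degenerate column zeroed
  expect_warning(W <- infer_causal_network(Y, n_trees = 50, seed = 1),
                 "constant")
  expect_identical(unname(W[, "c1"]), c(0, 0))
  expect_equal(sum(W[, "c2"]), 1)
})

test_that("network columns are normalized and weights non-negative", {
  sim <- simulate_dbn_dataset(4, T_len = 1500, seed = 8)
  W <- infer_causal_network(sim$states, n_trees = 200, seed = 2)
  expect_true(all(W >= 0))
  expect_equal(unname(colSums(W)), rep(1, 4))
})

test_that("time shuffling destroys the recovered structure", {
  sim <- simulate_dbn_dataset(5, T_len = 2000, seed = 16)
  W <- infer_causal_network(sim$states, n_trees = 300, seed = 4)
  auc <- edge_auc(W, sim$truth)
  expect_equal(auc, 1)
  set.seed(6)
  Ys <- sim$states[, sample(ncol(sim$states))]
  Ws <- infer_causal_network(Ys, n_trees = 300, seed = 4)
  auc_s <- edge_auc(Ws, sim$truth)
  expect_lt(abs(auc_s - 0.5), 0.25)
})

test_that("strong links are the weights strictly above the median", {
  W1 <- matrix(0.25, 2, 2)
  expect_identical(nrow(strong_links(W1)), 0L)
  W2 <- matrix(c(0.9, 0.1, 0.1, 0.1), 2, 2)
  sl <- strong_links(W2)
  expect_identical(nrow(sl), 1L)
  expect_equal(sl$weight, 0.9)
  # 16 distinct weights: exactly the 8 above the median, sort-oracle order
  set.seed(23)
  W3 <- matrix(sample(seq(0.01, 0.16, by = 0.01)), 4, 4)
  sl3 <- strong_links(W3)
  expect_identical(nrow(sl3), 8L)
  expect_equal(sl3$weight, sort(W3[W3 > median(W3)], decreasing = TRUE))
})

test_that("edge lists round-trip through three-column text", {
  set.seed(9)
  W <- matrix(runif(9), 3, 3, dimnames = list(paste0("c", 1:3),
                                              paste0("c", 1:3)))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_edge_list(W, f)
  W2 <- read_edge_list(f)
  expect_equal(unclass(W2)[rownames(W), colnames(W)], W)
})
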