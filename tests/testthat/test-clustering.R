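test_that("k = P-1 gives the complete graph; blocks stay unlinked", {
  set.seed(3)
  E <- event_matrix(matrix(rbinom(8 * 30, 1, 0.5), 8, 30))
  g <- build_neighbor_graph(E, k = 7)
  expect_equal(igraph::ecount(g), choose(8, 2))
  expect_equal(igraph::vcount(g), 8)
  # identical rows within blocks, maximal distance between: no cross edges
  Eb <- event_matrix(two_block_matrix(5, 20))
  gb <- build_neighbor_graph(Eb, k = 3)
  el <- igraph::as_edgelist(gb, names = FALSE)
  expect_true(all((el[, 1] <= 5) == (el[, 2] <= 5)))
})

test_that("neighbour graph matches the brute-force k-NN oracle", {
  set.seed(11)
  v <- matrix(rbinom(20 * 50, 1, 0.3), 20, 50)
  g <- build_neighbor_graph(event_matrix(v), k = 4)
  got <- igraph::as_edgelist(g, names = FALSE)
  got <- unique(t(apply(got, 1, sort)))
  storage.mode(got) <- "integer"
  want <- brute_knn_edges(v, 4)
  storage.mode(want) <- "integer"
  expect_identical(got[order(got[, 1], got[, 2]), ],
                   want[order(want[, 1], want[, 2]), ])
})

test_that("walktrap separates planted communities and cuts by modularity", {
  # two 5-cliques joined by one edge
  g <- igraph::make_full_graph(5) + igraph::make_full_graph(5)
  g <- igraph::add_edges(g, c(1, 6))
  part <- walktrap_partition(g)
  expect_identical(attr(part, "K"), 2L)
  expect_identical(length(unique(part[1:5])), 1L)
  expect_identical(length(unique(part[6:10])), 1L)
  expect_false(part[1] == part[6])
  # a single clique is one community
  part1 <- walktrap_partition(igraph::make_full_graph(6))
  expect_identical(attr(part1, "K"), 1L)
  # modularity at the cut beats the trivial partitions
  m_cut <- igraph::modularity(g, part)
  expect_gt(m_cut, igraph::modularity(g, rep(1, 10)))
  expect_gt(m_cut, igraph::modularity(g, 1:10))
})

test_that("edgeless graphs fall back to singletons with a warning", {
  g <- igraph::make_empty_graph(4, directed = FALSE)
  expect_warning(part <- walktrap_partition(g), "own cluster")
  expect_identical(as.integer(part), 1:4)
  expect_identical(attr(part, "K"), 4L)
})

test_that("disconnected graphs are partitioned per component", {
  g <- igraph::make_full_graph(4) + igraph::make_full_graph(3) +
    igraph::make_empty_graph(1, directed = FALSE)
  part <- walktrap_partition(g)
  expect_identical(attr(part, "K"), 3L)
  expect_identical(length(unique(part)), 3L)
})

test_that("noise-free clusters are recovered exactly for any valid k", {
  sim <- simulate_dbn_dataset(4, T_len = 300, neurons_per_cluster = 6,
                              lambda = 0, seed = 9)
  for (k in c(3, 5)) {
    part <- cluster_neurons(sim$events, k = k)
    expect_equal(rand_index(part, sim$partition), 1)
    expect_identical(attr(part, "K"), 4L)
  }
  # automatic neighbour selection finds the same structure
  part <- cluster_neurons(sim$events)
  expect_equal(rand_index(part, sim$partition), 1)
})

test_that("clustering is equivariant under neuron permutation", {
  sim <- simulate_dbn_dataset(3, T_len = 600, neurons_per_cluster = 8,
                              lambda = 0.1, seed = 5,
                              parents_range = c(1, 2))
  part <- cluster_neurons(sim$events, k = 6)
  set.seed(31)
  perm <- sample(nrow(sim$events))
  Ep <- event_matrix(unclass(sim$events)[perm, ],
                     neuron_ids = rownames(sim$events)[perm])
  part_p <- cluster_neurons(Ep, k = 6)
  expect_equal(rand_index(part_p, part[perm]), 1)
})

test_that("partitions round-trip through two-column text", {
  part <- c(a = 1L, b = 2L, c = 1L, d = 3L)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_partition(part, f)
  got <- read_partition(f)
  expect_identical(got[names(part)], part)
})
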