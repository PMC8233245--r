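# Small fixtures and independent oracles shared across test files.

# Deterministic toy event matrix: two blocks of identical rows.
two_block_matrix <- function(block_size = 5, T_len = 20) {
  rbind(
    matrix(0L, block_size, T_len),
    matrix(1L, block_size, T_len)
  )
}

# Brute-force k-NN edge set (union-symmetrized), ties to the lower index.
# Independent of the package's graph code: plain loops over the full
# distance matrix.
brute_knn_edges <- function(v, k) {
  P <- nrow(v)
  D <- matrix(0, P, P)
  for (i in 1:P) for (j in 1:P) D[i, j] <- sum(v[i, ] != v[j, ])
  edges <- matrix(integer(0), ncol = 2)
  for (i in 1:P) {
    cand <- setdiff(1:P, i)
    d <- D[i, cand]
    nn <- cand[order(d, cand)][1:k]
    for (j in nn) edges <- rbind(edges, sort(c(i, j)))
  }
  unique(edges)
}

# Brute-force mean silhouette with Hamming distances (direct formula).
brute_silhouette <- function(v, part) {
  P <- nrow(v)
  D <- matrix(0, P, P)
  for (i in 1:P) for (j in 1:P) D[i, j] <- sum(v[i, ] != v[j, ])
  s <- numeric(P)
  for (i in 1:P) {
    own <- setdiff(which(part == part[i]), i)
    if (length(own) == 0) { s[i] <- 0; next }
    a <- mean(D[i, own])
    b <- min(vapply(setdiff(unique(part), part[i]),
                    function(cl) mean(D[i, part == cl]), numeric(1)))
    s[i] <- if (max(a, b) == 0) 0 else (b - a) / max(a, b)
  }
  mean(s)
}

# Brute-force Rand index by explicit pair enumeration.
brute_rand <- function(p1, p2) {
  n <- length(p1)
  agree <- 0; total <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    total <- total + 1
    same1 <- p1[i] == p1[j]
    same2 <- p2[i] == p2[j]
    if (same1 == same2) agree <- agree + 1
  }
  agree / total
}

# Brute-force AUC by pair counting over all (positive, negative) pairs.
brute_auc <- function(w_pos, w_neg) {
  tot <- 0
  for (p in w_pos) for (q in w_neg)
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  tot / (length(w_pos) * length(w_neg))
}

# A tiny deterministic chain network: node i+1 copies node i.
copy_chain_dbn <- function(K) {
  dbn <- random_ground_truth(K, parents_range = c(0, 0), seed = 1)
  for (i in 2:K) {
    dbn$parents[[i]] <- i - 1L
    dbn$gain[[i]] <- 1
  }
  dbn$base[] <- 0
  dbn$base[1] <- 0.5
  dbn$clip <- c(0, 1)
  dbn$p0[] <- 0.5
  dbn
}
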