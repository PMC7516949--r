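# shared fixtures, built in code

# unit-weight complete digraph on n nodes
complete_digraph <- function(n) {
  W <- matrix(1, n, n)
  diag(W) <- 0
  weighted_digraph(W)
}

# two directed cliques of size `m` with no links between them
two_clique_graph <- function(m) {
  W <- matrix(0, 2 * m, 2 * m)
  W[seq_len(m), seq_len(m)] <- 1
  W[m + seq_len(m), m + seq_len(m)] <- 1
  diag(W) <- 0
  weighted_digraph(W)
}

# planted two-block digraph: strong intra-block, weak inter-block weights
two_block_graph <- function(m = 6, intra = c(0.7, 1), inter = c(0.05, 0.15),
                            p_intra = 0.9, p_inter = 0.5, seed = 1) {
  set.seed(seed)
  n <- 2 * m
  W <- matrix(0, n, n)
  block <- rep(1:2, each = m)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    if (block[i] == block[j]) {
      if (runif(1) < p_intra) W[i, j] <- runif(1, intra[1], intra[2])
    } else {
      if (runif(1) < p_inter) W[i, j] <- runif(1, inter[1], inter[2])
    }
  }
  list(graph = weighted_digraph(W), block = block)
}

# light embedding configuration for cohort-scale tests (the package defaults
# are heavier than these property checks need)
light_embedding <- function(seed = NULL, knn_k = 15) {
  embedding_config(dim = 16, walks_per_node = 5, walk_length = 20,
                   window = 4, epochs = 2, knn_k = knn_k, seed = seed)
}

expect_rrw_equal <- function(a, b, tol = 1e-12) {
  expect_identical(a$We, b$We)
  expect_identical(a$argmax_k, b$argmax_k)
  expect_identical(a$argmax_l, b$argmax_l)
  expect_equal(a$We_prime, b$We_prime, tolerance = tol)
  expect_equal(a$We_dprime, b$We_dprime, tolerance = tol)
}
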