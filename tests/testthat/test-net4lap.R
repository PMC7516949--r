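test_that("random walks respect forced transitions and return policies", {
  # two-node graph with a single edge 1 -> 2: walks from 1 either halt at 2
  # or bounce back along the return policy; only nodes {1, 2} ever appear
  W <- matrix(0, 2, 2); W[1, 2] <- 1
  cfg <- embedding_config(walks_per_node = 5, walk_length = 10,
                          return_prob = 0.5, seed = 1)
  walks <- sample_walks(weighted_digraph(W), cfg)
  from1 <- walks[vapply(walks, `[`, integer(1), 1) == 1]
  for (w in from1) {
    expect_true(all(w %in% c(1L, 2L)))
    expect_true(all(abs(diff(w)) == 1)) # strict alternation 1,2,1,2,...
  }

  # return_prob = 0 on a directed cycle: deterministic traversal
  n <- 5
  W <- matrix(0, n, n)
  W[cbind(1:n, c(2:n, 1))] <- 1
  cfg <- embedding_config(walks_per_node = 1, walk_length = 11,
                          return_prob = 0, seed = 2)
  walks <- sample_walks(weighted_digraph(W), cfg)
  for (w in walks)
    expect_equal(w[-1], ((w[-length(w)]) %% n) + 1L)

  # isolated node: length-1 walks
  W <- matrix(0, 3, 3); W[1, 2] <- 1
  walks <- sample_walks(weighted_digraph(W), embedding_config(
    walks_per_node = 2, walk_length = 5, return_prob = 0, seed = 3))
  starts3 <- walks[vapply(walks, `[`, integer(1), 1) == 3]
  expect_true(all(lengths(starts3) == 1))
})

test_that("walk transitions are proportional to outgoing weights", {
  # fixed 5-node weighted graph; compare first-step frequencies from node 1
  # against the exact transition distribution, within 3 standard errors
  W <- matrix(0, 5, 5)
  W[1, 2:5] <- c(0.1, 0.2, 0.3, 0.4)
  W[2:5, 1] <- 1
  g <- weighted_digraph(W)
  cfg <- embedding_config(walks_per_node = 2000, walk_length = 2, window = 1,
                          return_prob = 0, seed = 4)
  walks <- sample_walks(g, cfg)
  first <- vapply(walks[vapply(walks, `[`, integer(1), 1) == 1],
                  `[`, integer(1), 2)
  p <- W[1, 2:5]
  for (j in 2:5) {
    phat <- mean(first == j)
    se <- sqrt(p[j - 1] * (1 - p[j - 1]) / length(first))
    expect_lt(abs(phat - p[j - 1]), 3 * se)
  }
})

test_that("embeddings are deterministic and structurally faithful", {
  g <- two_clique_graph(10)
  cfg <- embedding_config(dim = 16, walks_per_node = 8, walk_length = 20,
                          window = 4, epochs = 3, seed = 5)
  walks <- sample_walks(g, cfg)
  e1 <- learn_embedding(walks, cfg, g$n_nodes)
  e2 <- learn_embedding(walks, cfg, g$n_nodes)
  expect_identical(e1$vectors, e2$vectors) # bitwise under a fixed seed

  # two disjoint cliques: within-clique inner products dominate
  X <- e1$vectors
  G <- tcrossprod(X)
  within <- c(G[1:10, 1:10][upper.tri(matrix(0, 10, 10))],
              G[11:20, 11:20][upper.tri(matrix(0, 10, 10))])
  between <- G[1:10, 11:20]
  expect_gt(mean(within), mean(between))
})

test_that("a uniform clique embeds nearly isotropically", {
  g <- complete_digraph(12)
  cfg <- embedding_config(dim = 16, walks_per_node = 10, walk_length = 20,
                          window = 4, epochs = 3, seed = 6)
  e <- learn_embedding(sample_walks(g, cfg), cfg, 12)
  D <- as.matrix(dist(e$vectors))
  d <- D[upper.tri(D)]
  expect_lt(sd(d) / mean(d), 0.5) # coefficient of variation of distances
})

test_that("embedding kNN rebuild follows geometry and kernel limits", {
  # 10 points on a line, knn_k = 3: each node links to its 3 line neighbours
  X <- cbind(1:10, 0)
  emb <- structure(list(vectors = X, node_ids = as.character(1:10)),
                   class = "node_embedding")
  g <- rebuild_knn(emb, embedding_config(knn_k = 3, sigma = 1))
  for (i in 1:10) {
    nb <- which(g$W[i, ] > 0)
    expected <- setdiff(order(abs((1:10) - i))[1:4], i)[1:3]
    expect_setequal(nb, expected)
  }

  # sigma -> Inf: all retained weights -> 1
  g <- rebuild_knn(emb, embedding_config(knn_k = 3, sigma = 1e12))
  expect_true(all(abs(g$W[g$W > 0] - 1) < 1e-9))

  # coincident vectors: weight exactly 1, ties resolved by node index
  X2 <- rbind(c(0, 0), c(0, 0), c(5, 0), c(6, 0))
  emb2 <- structure(list(vectors = X2, node_ids = as.character(1:4)),
                    class = "node_embedding")
  g2 <- rebuild_knn(emb2, embedding_config(knn_k = 1, sigma = 1))
  expect_equal(g2$W[1, 2], 1)
  expect_equal(g2$W[2, 1], 1)
})

test_that("Katz centrality matches closed forms and the truncated series", {
  n <- 4
  cfg <- regularization_config(katz_attenuation = 0.2)
  # empty graph: baseline everywhere
  expect_equal(katz_centrality(weighted_digraph(matrix(0, n, n)), cfg),
               rep(1, n))

  # directed 3-cycle: all centralities baseline / (1 - a) by symmetry
  W <- matrix(0, 3, 3); W[cbind(1:3, c(2, 3, 1))] <- 1
  expect_equal(katz_centrality(weighted_digraph(W), cfg), rep(1 / 0.8, 3))

  # star (all leaves -> hub): hub dominates; closed form equals the series
  W <- matrix(0, 6, 6); W[2:6, 1] <- 1
  cfg <- regularization_config(katz_attenuation = 0.1)
  C <- katz_centrality(weighted_digraph(W), cfg)
  expect_gt(C[1], C[2])
  series <- rep(1, 6)
  term <- rep(1, 6)
  for (k in 1:50) {
    term <- 0.1 * t(W) %*% term
    series <- series + term
  }
  expect_equal(C, as.vector(series), tolerance = 1e-10)

  # divergent attenuation is rejected with the spectral radius in the message
  W <- matrix(0, 3, 3); W[cbind(1:3, c(2, 3, 1))] <- 1
  expect_error(katz_centrality(weighted_digraph(W),
                               regularization_config(katz_attenuation = 1.5)),
               "spectral radius")
})

test_that("Laplacian regularization solves the ranking optimization", {
  # edgeless graph: A = I exactly
  A <- laplacian_regularize(weighted_digraph(matrix(0, 4, 4)),
                            regularization_config(alpha = 2))
  expect_equal(unclass(A), diag(4), tolerance = 1e-12)

  # alpha -> large: A -> I
  g <- generate_random_digraph(10, 0.4, seed = 9)
  A <- laplacian_regularize(g, regularization_config(alpha = 1e6))
  expect_lt(max(abs(unclass(A) - diag(10))), 1e-3)

  # ||A - I|| monotonically decreasing in alpha
  gaps <- vapply(c(0.1, 1, 10, 100), function(al)
    max(abs(unclass(laplacian_regularize(g,
      regularization_config(alpha = al))) - diag(10))), numeric(1))
  expect_true(all(diff(gaps) < 0))

  expect_error(regularization_config(alpha = 0), "alpha")

  # 4-node path: the solver matches direct gradient-descent minimization of
  # Q(A) = alpha tr((A-I)' Lam (A-I)) + tr(A' L A)
  W <- matrix(0, 4, 4)
  W[cbind(1:3, 2:4)] <- 1; W[cbind(2:4, 1:3)] <- 1
  g <- weighted_digraph(W)
  alpha <- 1
  A <- unclass(laplacian_regularize(g, regularization_config(alpha = alpha)))
  L <- diag(rowSums(W)) - W
  Agd <- diag(4)
  for (it in 1:8000) {
    grad <- 2 * alpha * (Agd - diag(4)) + 2 * L %*% Agd
    Agd <- Agd - 0.05 * grad
  }
  expect_equal(A, Agd, tolerance = 1e-6)
})

test_that("centrality modulation shifts absorption toward low-centrality nodes", {
  g <- generate_random_digraph(8, 0.5, seed = 14)
  cfg <- regularization_config(alpha = 1)
  C <- katz_centrality(g, cfg)
  A0 <- unclass(laplacian_regularize(g, cfg)) # uniform centrality
  A1 <- unclass(laplacian_regularize(g, cfg, C))
  expect_false(isTRUE(all.equal(A0, A1)))
  # rows remain within [0, 1]-ish absorption scale (M-matrix inverse)
  expect_true(all(A1 >= -1e-12))
})

test_that("precondition composes the stages deterministically and densifies", {
  g <- generate_random_digraph(48, 0.05, seed = 21)
  cfg <- light_embedding(seed = 22, knn_k = 8)
  rcfg <- regularization_config()

  # rerank_cycles = 0: the rebuilt embedding-kNN graph, no regularization
  g0 <- precondition(g, cfg, rcfg, rerank_cycles = 0)
  walks <- sample_walks(g, cfg)
  manual <- rebuild_knn(learn_embedding(walks, cfg, g$n_nodes), cfg)
  expect_identical(g0$W, manual$W)

  # determinism of the full cycle
  p1 <- precondition(g, cfg, rcfg)
  p2 <- precondition(g, cfg, rcfg)
  expect_identical(p1$W, p2$W)

  # densification of sparse inputs, on average over a small cohort
  set.seed(23)
  gain <- replicate(8, {
    gs <- generate_random_digraph(48, runif(1, 0.02, 0.1))
    n_edges(precondition(gs, light_embedding(seed = 24, knn_k = 8))) - n_edges(gs)
  })
  expect_gt(mean(gain), 0)
})

test_that("preconditioning does not worsen local outgoing-weight isotropy", {
  set.seed(25)
  cv_out <- function(g) {
    cvs <- apply(g$W, 1, function(w) {
      w <- w[w > 0]
      if (length(w) < 2) return(NA_real_)
      sd(w) / mean(w)
    })
    mean(cvs, na.rm = TRUE)
  }
  deltas <- replicate(6, {
    g <- generate_random_digraph(48, runif(1, 0.1, 0.3))
    cv_out(precondition(g, light_embedding(seed = 26, knn_k = 8))) - cv_out(g)
  })
  expect_lte(mean(deltas), 0)
})
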