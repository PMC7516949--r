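#' Configuration for the neural-embedding stage
#'
#' Hyperparameters of the random-walk sampling, skip-gram SGD and
#' embedding-space kNN rebuild used by [precondition()].
#'
#' @param dim embedding dimension (>= 2).
#' @param walks_per_node random walks started from every node.
#' @param walk_length steps per walk (must be >= `window`).
#' @param return_prob probability of stepping back to the previous node at
#'   each step (the walk's return policy), in `[0, 1]`.
#' @param window skip-gram context window (co-occurrence radius in a walk).
#' @param negatives negative samples per positive pair.
#' @param epochs SGD passes over the walk corpus.
#' @param learning_rate initial SGD learning rate (decays linearly).
#' @param sigma bandwidth of the Gaussian affinity `exp(-||xi - xj||^2 / sigma)`
#'   in the rebuilt kNN graph; `NULL` self-tunes to the median squared
#'   embedding distance.
#' @param knn_k out-neighbours per node in the rebuilt graph.
#' @param seed integer seed controlling walks and SGD (single-threaded, so a
#'   fixed seed gives bitwise-identical embeddings).
#' @return a list of class `embedding_config`.
#' @export
embedding_config <- function(dim = 64, walks_per_node = 10, walk_length = 40,
                             return_prob = 0.15, window = 5, negatives = 5,
                             epochs = 5, learning_rate = 0.025, sigma = NULL,
                             knn_k = 15, seed = NULL) {
  if (dim < 2) stop("dim must be >= 2")
  if (walk_length < window) stop("walk_length must be >= window")
  if (return_prob < 0 || return_prob > 1) stop("return_prob must lie in [0, 1]")
  structure(list(dim = dim, walks_per_node = walks_per_node,
                 walk_length = walk_length, return_prob = return_prob,
                 window = window, negatives = negatives, epochs = epochs,
                 learning_rate = learning_rate, sigma = sigma, knn_k = knn_k,
                 seed = seed), class = "embedding_config")
}

#' Configuration for the Laplacian-regularization stage
#'
#' @param alpha positive regularization strength; large `alpha` pins the
#'   ranking matrix to the identity.
#' @param lambda_mode `"identity"` (Lambda = I, suited to dense graphs) or
#'   `"degree"` (Lambda = D', suited to locally sparse graphs).
#' @param gamma weight of the smoothness (harmonic) term; default 1.
#' @param katz_attenuation attenuation `a` of the Katz series; must be below
#'   `1 / spectral-radius(W)`. `NULL` self-tunes to `0.85 / rho(W)`.
#' @param katz_baseline additive baseline of the Katz series (default 1).
#' @return a list of class `regularization_config`.
#' @export
regularization_config <- function(alpha = 1,
                                  lambda_mode = c("identity", "degree"),
                                  gamma = 1, katz_attenuation = NULL,
                                  katz_baseline = 1) {
  lambda_mode <- match.arg(lambda_mode)
  if (alpha <= 0) stop("alpha must be positive")
  if (gamma <= 0) stop("gamma must be positive")
  structure(list(alpha = alpha, lambda_mode = lambda_mode, gamma = gamma,
                 katz_attenuation = katz_attenuation,
                 katz_baseline = katz_baseline),
            class = "regularization_config")
}

#' Sample random walks with a return policy
#'
#' Starts `walks_per_node` walks from every node. At each step the walker
#' returns to its previous position with probability `return_prob`; otherwise
#' it moves to an out-neighbour with probability proportional to the outgoing
#' edge weight. Walks halt early at sink nodes; isolated nodes yield
#' length-1 walks.
#'
#' @param g a [weighted_digraph()].
#' @param cfg an [embedding_config()].
#' @return list of integer vectors (node indices, 1-based).
#' @export
sample_walks <- function(g, cfg = embedding_config()) {
  W <- as_adjacency(g)
  n <- nrow(W)
  if (n == 0) stop("graph is empty")
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  walk_core(W, cfg$walks_per_node, cfg$walk_length, cfg$return_prob)
}

#' Learn a node embedding from walks (skip-gram with negative sampling)
#'
#' Optimizes the skip-gram objective over node co-occurrence pairs within a
#' window along each walk, by single-threaded SGD with negative sampling.
#' The log-probability of a context node is proportional to the inner
#' product of the two node vectors.
#'
#' @param walks list of integer node sequences from [sample_walks()].
#' @param cfg an [embedding_config()].
#' @param n_nodes total node count (nodes absent from all walks receive a
#'   zero vector, with a warning).
#' @return a `node_embedding`: list with `vectors` (n x dim matrix) and
#'   `node_ids`.
#' @export
learn_embedding <- function(walks, cfg = embedding_config(), n_nodes) {
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  seen <- logical(n_nodes)
  for (w in walks) seen[w] <- TRUE
  if (!all(seen))
    warning(sprintf("%d node(s) absent from all walks: zero-vector embedding",
                    sum(!seen)))
  vec <- sgd_skipgram(walks, n_nodes, cfg$dim, cfg$window, cfg$negatives,
                      cfg$epochs, cfg$learning_rate)
  vec[!seen, ] <- 0
  structure(list(vectors = vec, node_ids = as.character(seq_len(n_nodes))),
            class = "node_embedding")
}

#' Rebuild a kNN graph from an embedding with a Gaussian affinity
#'
#' Connects every node to its `knn_k` nearest neighbours in embedding space
#' (squared Euclidean distance; self excluded; ties by node index), with edge
#' weight `exp(-||xi - xj||^2 / sigma)`. The Gaussian kernel is the concrete
#' sub-Gaussian affinity; `sigma` self-tunes to the median squared pairwise
#' distance when not set.
#'
#' @param emb a `node_embedding`.
#' @param cfg an [embedding_config()].
#' @return a [weighted_digraph()] (each node has out-degree `knn_k`).
#' @export
rebuild_knn <- function(emb, cfg = embedding_config()) {
  X <- emb$vectors
  if (any(!is.finite(X))) stop("embedding must be finite")
  n <- nrow(X)
  sq <- rowSums(X^2)
  D2 <- outer(sq, sq, "+") - 2 * tcrossprod(X)
  D2[D2 < 0] <- 0 # numerical guard
  sigma <- cfg$sigma
  if (is.null(sigma)) {
    off <- D2[upper.tri(D2)]
    sigma <- median(off)
    if (!is.finite(sigma) || sigma <= 0) sigma <- 1
  }
  k <- min(cfg$knn_k, n - 1)
  W <- matrix(0, n, n)
  for (i in seq_len(n)) {
    d <- D2[i, ]
    d[i] <- Inf
    nb <- order(d, seq_len(n))[seq_len(k)] # ties by node index
    W[i, nb] <- exp(-D2[i, nb] / sigma)
  }
  weighted_digraph(W, node_ids = emb$node_ids)
}

#' Katz centrality of a weighted digraph
#'
#' The attenuated count of all incoming walks of every length:
#' `C = baseline * (I - a W^T)^{-1} 1`, equal to the geometric series
#' `baseline * sum_k a^k (W^T)^k 1`, convergent for `a < 1 / rho(W)`.
#'
#' @param g a [weighted_digraph()].
#' @param cfg a [regularization_config()]; `katz_attenuation = NULL`
#'   self-tunes to `0.85 / rho(W)`.
#' @return numeric vector of strictly positive centralities.
#' @export
katz_centrality <- function(g, cfg = regularization_config()) {
  W <- as_adjacency(g)
  n <- nrow(W)
  if (all(W == 0)) return(rep(cfg$katz_baseline, n))
  rho <- max(Mod(eigen(W, only.values = TRUE)$values))
  a <- cfg$katz_attenuation
  if (is.null(a)) a <- if (rho > 0) 0.85 / rho else 0.5
  if (rho > 0 && a >= 1 / rho)
    stop(sprintf("Katz series diverges: attenuation %.4g >= 1/spectral radius (rho = %.4g)",
                 a, rho))
  as.vector(solve(diag(n) - a * t(W), rep(cfg$katz_baseline, n)))
}

#' Laplacian-regularized ranking matrix with centrality-modulated affinities
#'
#' Solves `(alpha Lambda + L) A = alpha Lambda`, where `L = D' - W'` is the
#' Laplacian of the symmetrized working graph `W' = max(W, W^T)` and
#' `Lambda = diag(lambda_i / C_i)` with `lambda_i = 1` (identity mode) or
#' `lambda_i = d'_i` (degree mode): high-centrality nodes absorb less, so the
#' global Katz centrality modulates the diffusion. `A` is the minimizer of
#' `alpha * tr((A - I)^T Lambda (A - I)) + gamma * tr(A^T L A)` at
#' `gamma = 1`, and tends to the identity as `alpha` grows.
#'
#' @param g a [weighted_digraph()] (symmetrized internally for this step).
#' @param cfg a [regularization_config()].
#' @param centrality positive centrality vector (e.g. [katz_centrality()]);
#'   defaults to all ones (no modulation).
#' @return n x n numeric ranking matrix of class `ranking_matrix`.
#' @export
laplacian_regularize <- function(g, cfg = regularization_config(),
                                 centrality = NULL) {
  W <- as_adjacency(g)
  n <- nrow(W)
  Ws <- pmax(W, t(W))
  dg <- rowSums(Ws)
  L <- diag(dg, n) - Ws
  if (is.null(centrality)) centrality <- rep(1, n)
  if (any(centrality <= 0)) stop("centrality must be strictly positive")
  lam <- if (cfg$lambda_mode == "identity") rep(1, n) else dg
  if (cfg$lambda_mode == "degree" && any(lam <= 0))
    stop("degree mode requires every node to have incident weight")
  lamc <- cfg$alpha * lam / centrality
  M <- diag(lamc, n) + cfg$gamma * L
  A <- solve(M, diag(lamc, n))
  structure(A, class = c("ranking_matrix", "matrix"))
}

#' Precondition a graph (net4Lap): embed, rebuild, regularize, re-rank
#'
#' Composes the full preconditioning cycle: random-walk sampling ->
#' skip-gram embedding -> embedding-space kNN rebuild -> Katz centrality ->
#' Laplacian-regularized ranking -> kNN graph over the ranking similarities.
#' The regularization works on the symmetrized rebuilt graph; directionality
#' is restored by masking the ranking matrix with the rebuilt graph's
#' directed support before the final kNN selection. With
#' `rerank_cycles = 0` the rebuilt embedding-kNN graph is returned without
#' regularization; extra cycles re-feed the re-ranked graph into the SGD
#' model.
#'
#' @param g input [weighted_digraph()].
#' @param ecfg an [embedding_config()].
#' @param rcfg a [regularization_config()].
#' @param rerank_cycles number of embed-regularize cycles (default 1).
#' @return a [weighted_digraph()].
#' @export
precondition <- function(g, ecfg = embedding_config(),
                         rcfg = regularization_config(), rerank_cycles = 1) {
  if (rerank_cycles < 0) stop("rerank_cycles must be >= 0")
  cur <- g
  cycles <- max(rerank_cycles, 1)
  for (cyc in seq_len(cycles)) {
    walks <- sample_walks(cur, ecfg)
    emb <- learn_embedding(walks, ecfg, cur$n_nodes)
    gk <- rebuild_knn(emb, ecfg)
    if (rerank_cycles == 0) return(gk)
    C <- katz_centrality(gk, rcfg)
    A <- laplacian_regularize(gk, rcfg, C)
    # ranking relationships define the new affinities: nodes whose absorption
    # profiles (rows of A) are close are similar, and the same sub-Gaussian
    # kernel as in the embedding step turns profile distances into weights
    P <- unclass(A)
    sq <- rowSums(P^2)
    D2 <- outer(sq, sq, "+") - 2 * tcrossprod(P)
    D2[D2 < 0] <- 0
    sig <- median(D2[upper.tri(D2)])
    if (!is.finite(sig) || sig <= 0) sig <- 1
    S <- exp(-D2 / sig)
    # restore directionality: candidates only on the rebuilt directed support
    S[gk$W == 0] <- 0
    diag(S) <- 0
    n <- nrow(S)
    k <- min(ecfg$knn_k, n - 1)
    Wnew <- matrix(0, n, n)
    for (i in seq_len(n)) {
      nz <- which(S[i, ] > 0)
      if (length(nz) == 0) next
      keep <- nz[order(-S[i, nz], nz)][seq_len(min(k, length(nz)))]
      Wnew[i, keep] <- S[i, keep]
    }
    cur <- weighted_digraph(Wnew, node_ids = g$node_ids)
  }
  cur
}
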