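#' Weighted degree used in the return-random-walk probabilities
#'
#' `d(v) = (in-strength(v) + out-strength(v)) / 2`: on a symmetric weight
#' matrix this equals the classic undirected weighted degree (each incident
#' edge counted once), and it treats the go and return legs of a walk on a
#' common scale on directed graphs. `d(v) = 0` exactly when `v` has no
#' incident weight.
#'
#' @param W nonnegative weight matrix.
#' @return numeric degree vector.
#' @export
rrw_degree <- function(W) {
  (rowSums(W) + colSums(W)) / 2
}

#' Two-step transition probability through a transit node
#'
#' `p_k(j | i) = W[i,k] W[k,j] / (d(i) d(j))`: the probability score of
#' walking from `i` to `j` in two steps via `k`, normalized by the endpoint
#' degrees.
#'
#' @param W weight matrix.
#' @param i,k,j 1-based node indices (origin, transit, destination).
#' @param d degree vector; defaults to [rrw_degree()] of `W`.
#' @return a nonnegative real; 0 whenever either hop weight is 0.
#' @export
two_step_prob <- function(W, i, k, j, d = rrw_degree(W)) {
  num <- W[i, k] * W[k, j]
  if (num == 0) return(0)
  den <- d[i] * d[j]
  if (den == 0) stop("degenerate node: zero degree with a nonzero two-step path")
  num / den
}

#' Return-random-walk score of one ordered pair
#'
#' Maximizes the product of the outgoing two-step probability via `k` and the
#' return two-step probability via `l != k`:
#' `We_ij = max_k max_{l != k} p_k(j|i) p_l(i|j)`.
#' When no valid `(k, l)` pair yields a positive product the score is 0 with
#' `NA` transit indices (the maximum over the empty set).
#'
#' @param W weight matrix.
#' @param i,j distinct 1-based node indices.
#' @param d degree vector; defaults to [rrw_degree()] of `W`.
#' @return list with `We` and the maximizing transits `k` and `l`
#'   (`NA` when `We = 0`).
#' @export
rrw_weight <- function(W, i, j, d = rrw_degree(W)) {
  if (i == j) stop("i and j must be distinct")
  res <- rrw_core(W, d)
  list(We = res$We[i, j], k = res$kstar[i, j], l = res$lstar[i, j])
}

rrw_gamma <- function(W, distance = c("inverse_weight", "hops")) {
  distance <- match.arg(distance)
  cost <- matrix(0, nrow(W), ncol(W))
  nz <- W > 0
  cost[nz] <- if (distance == "inverse_weight") 1 / W[nz] else 1
  dijkstra_all(cost)
}

# shared by apply_directed_rrw and the attenuation/ratio helpers:
# hop-weight sums along the maximizing go (i->k->j) and return (j->l->i) legs
rrw_leg_sums <- function(W, kstar, lstar) {
  n <- nrow(W)
  nz <- which(!is.na(kstar))
  go <- matrix(0, n, n); back <- matrix(0, n, n)
  if (length(nz)) {
    ij <- arrayInd(nz, c(n, n))
    i <- ij[, 1]; j <- ij[, 2]; k <- kstar[nz]; l <- lstar[nz]
    go[nz] <- W[cbind(i, k)] + W[cbind(k, j)]
    back[nz] <- W[cbind(j, l)] + W[cbind(l, i)]
  }
  list(go = go, back = back)
}

#' Shortest-path attenuation of the RRW scores
#'
#' `We'_ij = We_ij * exp(-gamma_ij / Path_ij)` (ratio form, the default),
#' where `Path_ij = W[i,k*] + W[k*,j] + W[j,l*] + W[l*,i]` sums the four hop
#' weights along the maximizing go-and-return cycle and `gamma_ij` is the
#' shortest-path distance from `i` to `j`. With inverse-weight hop costs a
#' weak path makes `gamma` large relative to `Path` and the score is strongly
#' attenuated. The product form `exp(-gamma * Path)` is available for
#' comparison.
#'
#' @param rrw an `rrw_result` from [apply_directed_rrw()].
#' @param W the original weight matrix.
#' @param exponent_form `"ratio"` (default) or `"product"`.
#' @param distance `"inverse_weight"` (hop cost `1/W`, default) or `"hops"`.
#' @return the attenuated matrix `We'`.
#' @export
path_attenuation <- function(rrw, W,
                             exponent_form = c("ratio", "product"),
                             distance = c("inverse_weight", "hops")) {
  exponent_form <- match.arg(exponent_form)
  distance <- match.arg(distance)
  legs <- rrw_leg_sums(W, rrw$argmax_k, rrw$argmax_l)
  gam <- rrw_gamma(W, distance)
  Path <- legs$go + legs$back
  Wp <- matrix(0, nrow(W), ncol(W))
  nz <- which(rrw$We > 0)
  expo <- if (exponent_form == "ratio") -gam[nz] / Path[nz] else -gam[nz] * Path[nz]
  Wp[nz] <- rrw$We[nz] * exp(expo)
  Wp[!is.finite(Wp)] <- 0 # unreachable pairs (gamma = Inf) are zeroed
  Wp
}

#' Outgoing/return imbalance factor applied to the attenuated scores
#'
#' `We''_ij = We'_ij * b_ij` with `b_ij = (W[i,k*] + W[k*,j]) / (W[j,l*] +
#' W[l*,i])`, the ratio of the go-leg to the return-leg weight sums on the
#' maximizing cycle. A low `b` flags an inter-class (noise) edge: reaching
#' `j` is easy but returning by a different transit is hard. `b` is applied
#' unclamped, so values above 1 (go stronger than return) amplify the score.
#'
#' @param rrw an `rrw_result`.
#' @param W the original weight matrix.
#' @param We_prime the attenuated matrix from [path_attenuation()]; defaults
#'   to `rrw$We_prime`.
#' @return the matrix `We''`.
#' @export
outgoing_return_ratio <- function(rrw, W, We_prime = rrw$We_prime) {
  legs <- rrw_leg_sums(W, rrw$argmax_k, rrw$argmax_l)
  Wpp <- matrix(0, nrow(W), ncol(W))
  nz <- which(We_prime > 0)
  if (length(nz)) {
    if (any(legs$back[nz] == 0))
      stop("internal inconsistency: zero return-leg weight with a nonzero score")
    Wpp[nz] <- We_prime[nz] * legs$go[nz] / legs$back[nz]
  }
  Wpp
}

#' Apply the directed Return Random Walk structural filter
#'
#' Computes the three reweighted matrices for every ordered pair: the raw
#' go-and-return score `We`, the shortest-path-attenuated `We'`, and the
#' go/return-imbalance-scaled `We''`, together with the maximizing transit
#' nodes. Intra-cluster links (easy to leave and return by distinct
#' transits) are reinforced; inter-cluster noise links are suppressed. The
#' result is typically denser than the input, since any pair joined by a
#' two-step go and return cycle receives a score even without a direct edge
#' (link prediction).
#'
#' @param g a [weighted_digraph()] or weight matrix.
#' @param exponent_form,distance see [path_attenuation()].
#' @return an `rrw_result`: list with matrices `We`, `We_prime`, `We_dprime`,
#'   integer matrices `argmax_k`, `argmax_l`, and the input `W`.
#' @examples
#' g <- generate_random_digraph(12, 0.4, seed = 1)
#' r <- apply_directed_rrw(g)
#' filtered <- weighted_digraph(r$We_dprime)
#' @export
apply_directed_rrw <- function(g, exponent_form = c("ratio", "product"),
                               distance = c("inverse_weight", "hops")) {
  exponent_form <- match.arg(exponent_form)
  distance <- match.arg(distance)
  W <- as_adjacency(g)
  if (nrow(W) == 0) stop("graph is empty")
  d <- rrw_degree(W)
  core <- rrw_core(W, d)
  res <- structure(list(We = core$We, argmax_k = core$kstar,
                        argmax_l = core$lstar, W = W),
                   class = "rrw_result")
  res$We_prime <- path_attenuation(res, W, exponent_form, distance)
  res$We_dprime <- outgoing_return_ratio(res, W)
  res
}

#' @export
print.rrw_result <- function(x, ...) {
  n <- nrow(x$We)
  cat(sprintf("directed RRW result: %d nodes\n", n))
  cat(sprintf("  nonzero scores: We %d, We' %d, We'' %d (of %d ordered pairs)\n",
              sum(x$We > 0), sum(x$We_prime > 0), sum(x$We_dprime > 0),
              n * (n - 1)))
  invisible(x)
}

#' Brute-force oracle for the directed Return Random Walk
#'
#' Exhaustively enumerates every `(k, l)` transit pair for every ordered
#' `(i, j)` and recomputes shortest paths with a hand-rolled Floyd-Warshall,
#' sharing no code with [apply_directed_rrw()]. Intentionally naive and
#' refused above 15 nodes; used to validate the fast implementation.
#'
#' @param W weight matrix (n <= 15).
#' @param exponent_form,distance see [path_attenuation()].
#' @return a list with the same `We`, `We_prime`, `We_dprime`, `argmax_k`,
#'   `argmax_l` fields as [apply_directed_rrw()].
#' @export
brute_force_rrw_oracle <- function(W, exponent_form = c("ratio", "product"),
                                   distance = c("inverse_weight", "hops")) {
  exponent_form <- match.arg(exponent_form)
  distance <- match.arg(distance)
  W <- as_adjacency(W)
  n <- nrow(W)
  if (n > 15) stop("oracle is intentionally naive: n must be <= 15")
  d <- (rowSums(W) + colSums(W)) / 2
  We <- matrix(0, n, n)
  kstar <- matrix(NA_integer_, n, n)
  lstar <- matrix(NA_integer_, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    best <- 0
    for (k in seq_len(n)) {
      pk <- W[i, k] * W[k, j] / (d[i] * d[j])
      if (is.na(pk) || pk <= 0) next
      for (l in seq_len(n)) {
        if (l == k) next
        pl <- W[j, l] * W[l, i] / (d[j] * d[i])
        if (is.na(pl) || pl <= 0) next
        p <- pk * pl
        if (p > best) {
          best <- p
          kstar[i, j] <- k
          lstar[i, j] <- l
        }
      }
    }
    We[i, j] <- best
  }
  # Floyd-Warshall shortest paths
  cost <- matrix(Inf, n, n)
  cost[W > 0] <- if (distance == "inverse_weight") 1 / W[W > 0] else 1
  diag(cost) <- 0
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n))
    if (cost[i, k] + cost[k, j] < cost[i, j])
      cost[i, j] <- cost[i, k] + cost[k, j]
  Wp <- matrix(0, n, n)
  Wpp <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (We[i, j] <= 0) next
    k <- kstar[i, j]; l <- lstar[i, j]
    path <- W[i, k] + W[k, j] + W[j, l] + W[l, i]
    e <- if (exponent_form == "ratio") -cost[i, j] / path else -cost[i, j] * path
    Wp[i, j] <- We[i, j] * exp(e)
    if (!is.finite(Wp[i, j])) Wp[i, j] <- 0
    if (Wp[i, j] > 0)
      Wpp[i, j] <- Wp[i, j] * (W[i, k] + W[k, j]) / (W[j, l] + W[l, i])
  }
  list(We = We, We_prime = Wp, We_dprime = Wpp,
       argmax_k = kstar, argmax_l = lstar, W = W)
}
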