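#' Time-lagged cross-correlation of two series
#'
#' Scans lags in `[-max_lag, max_lag]`, computes the Pearson correlation of
#' the aligned overlap at each lag, and returns the lag maximizing the
#' absolute correlation. A positive lag means `x` leads `y` (i.e. `y(t)`
#' tracks `x(t - lag)`). Ties on |correlation| are broken toward the smallest
#' |lag|, positive before negative, so the zero-lag solution is preferred for
#' truly synchronous pairs.
#'
#' @param x,y numeric series of equal length (> `2 * max_lag`).
#' @param max_lag maximum lag magnitude scanned (default 3 samples).
#' @return list with `corr` (signed Pearson correlation at the chosen lag),
#'   `lag`, and `degenerate` (`TRUE` when either overlap was constant, in
#'   which case `corr = 0` and a warning is emitted).
#' @export
lagged_cross_correlation <- function(x, y, max_lag = 3) {
  n <- length(x)
  if (length(y) != n) stop("series must have equal length")
  if (n <= 2 * max_lag) stop("series length must exceed 2 * max_lag")
  lags <- c(0, as.vector(rbind(seq_len(max_lag), -seq_len(max_lag))))
  if (max_lag == 0) lags <- 0L
  best <- list(corr = 0, lag = 0L, degenerate = FALSE)
  best_abs <- -Inf
  any_degenerate <- FALSE
  for (L in lags) {
    if (L >= 0) { xs <- x[seq_len(n - L)]; ys <- y[seq_len(n - L) + L] }
    else { xs <- x[seq_len(n + L) - L]; ys <- y[seq_len(n + L)] }
    if (sd(xs) == 0 || sd(ys) == 0) { any_degenerate <- TRUE; next }
    r <- cor(xs, ys)
    if (abs(r) > best_abs) { # strict: earlier (smaller |lag|) wins ties
      best_abs <- abs(r)
      best <- list(corr = r, lag = as.integer(L), degenerate = FALSE)
    }
  }
  if (best_abs == -Inf) {
    warning("constant series: correlation undefined, reported as 0")
    return(list(corr = 0, lag = 0L, degenerate = TRUE))
  }
  if (any_degenerate) best$degenerate <- TRUE
  best
}

#' Build a directed weighted kNN graph from ROI time series
#'
#' For every pair of ROIs the maximal-|correlation| lag is found with
#' [lagged_cross_correlation()]; the pair contributes a candidate edge of
#' weight |correlation| directed from the leading to the lagging region
#' (magnitude only — the lag sign, not the correlation sign, carries the
#' direction). Zero-lag pairs contribute both directions (a bidirectional
#' connection). Each node then keeps only its `k` strongest outgoing
#' candidates.
#'
#' @param ts a `timeseries_set` (see [generate_bold_timeseries()],
#'   [read_timeseries_csv()]).
#' @param k out-neighbours kept per node (default 15).
#' @param max_lag lag window for the cross-correlations (default 3).
#' @return a [weighted_digraph()] with the ROI names as node ids.
#' @export
build_directed_graph <- function(ts, k = 15, max_lag = 3) {
  S <- ts$series
  n <- ncol(S)
  if (k >= n) stop("k must be smaller than the number of ROIs")
  W <- matrix(0, n, n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      cc <- lagged_cross_correlation(S[, i], S[, j], max_lag)
      w <- abs(cc$corr)
      if (w == 0) next
      if (cc$lag > 0) W[i, j] <- w
      else if (cc$lag < 0) W[j, i] <- w
      else { W[i, j] <- w; W[j, i] <- w }
    }
  }
  # per-node out-kNN: keep the k strongest outgoing candidates, ties by target
  for (i in seq_len(n)) {
    nz <- which(W[i, ] > 0)
    if (length(nz) > k) {
      keep <- nz[order(-W[i, nz], nz)][seq_len(k)]
      drop <- setdiff(nz, keep)
      W[i, drop] <- 0
    }
  }
  weighted_digraph(W, node_ids = ts$roi_names)
}

#' Binarize a weighted digraph by retaining the top-c fraction of weights
#'
#' Keeps exactly `ceiling(c * nnz)` largest-weight edges (over that graph's
#' nonzero weights) as 1s and zeroes the rest. Ties at the cutoff are broken
#' by (source, target) lexicographic order for determinism.
#'
#' @param g a [weighted_digraph()].
#' @param c fraction of nonzero weights retained, in (0, 1]; default 0.40.
#' @return a [binary_digraph()].
#' @export
threshold_top_c <- function(g, c = 0.40) {
  if (c <= 0 || c > 1) stop("c must lie in (0, 1]")
  W <- as_adjacency(g)
  n <- nrow(W)
  A <- matrix(0, n, n)
  idx <- which(W > 0, arr.ind = TRUE)
  if (nrow(idx) > 0) {
    m <- ceiling(c * nrow(idx))
    ord <- order(-W[idx], idx[, 1], idx[, 2])
    keep <- idx[ord[seq_len(m)], , drop = FALSE]
    A[keep] <- 1
  }
  ids <- if (inherits(g, "weighted_digraph")) g$node_ids else NULL
  binary_digraph(A, node_ids = ids)
}
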