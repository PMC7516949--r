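#' Weighted directed graph over ROI nodes
#'
#' Light container for the nonnegative weighted adjacency matrix that every
#' pipeline stage transforms. Row `i`, column `j` holds the weight of the
#' directed edge `i -> j`. The diagonal is forced to zero (self-connections
#' carry no information about inter-regional coupling).
#'
#' @param W square numeric matrix of nonnegative finite weights.
#' @param node_ids optional character vector of node (ROI) names; defaults to
#'   `"V1"`, ..., `"Vn"` style integer labels.
#' @return an object of class `weighted_digraph` with elements `W`, `n_nodes`
#'   and `node_ids`.
#' @examples
#' g <- weighted_digraph(matrix(c(0, 1, 0.5, 0), 2, 2, byrow = TRUE))
#' n_edges(g)
#' @export
weighted_digraph <- function(W, node_ids = NULL) {
  W <- as.matrix(W)
  if (nrow(W) != ncol(W)) stop("adjacency matrix must be square")
  if (!is.numeric(W) || any(!is.finite(W))) stop("weights must be finite numbers")
  if (any(W < 0)) stop("weights must be nonnegative")
  diag(W) <- 0
  dimnames(W) <- NULL
  n <- nrow(W)
  ids <- if (is.null(node_ids)) as.character(seq_len(n)) else as.character(node_ids)
  if (length(ids) != n) stop("node_ids length must match the number of nodes")
  structure(list(W = W, n_nodes = n, node_ids = ids), class = "weighted_digraph")
}

#' Binary directed graph
#'
#' @param A square matrix with entries in \{0, 1\}; diagonal forced to zero.
#' @param node_ids optional node names.
#' @return an object of class `binary_digraph` with elements `A`, `n_nodes`,
#'   `node_ids`.
#' @export
binary_digraph <- function(A, node_ids = NULL) {
  A <- as.matrix(A)
  if (nrow(A) != ncol(A)) stop("adjacency matrix must be square")
  if (!all(A %in% c(0, 1))) stop("entries must be 0 or 1")
  diag(A) <- 0
  dimnames(A) <- NULL
  storage.mode(A) <- "double"
  n <- nrow(A)
  ids <- if (is.null(node_ids)) as.character(seq_len(n)) else as.character(node_ids)
  structure(list(A = A, n_nodes = n, node_ids = ids), class = "binary_digraph")
}

as_adjacency <- function(g) {
  if (inherits(g, "weighted_digraph")) return(g$W)
  if (inherits(g, "binary_digraph")) return(g$A)
  if (is.matrix(g)) return(g)
  stop("expected a weighted_digraph, binary_digraph or matrix")
}

#' Number of (nonzero) directed edges
#' @param g a `weighted_digraph` or `binary_digraph`.
#' @return integer edge count.
#' @export
n_edges <- function(g) sum(as_adjacency(g) > 0)

#' Edge density over ordered node pairs
#' @param g a `weighted_digraph` or `binary_digraph`.
#' @return fraction of the `n*(n-1)` ordered pairs carrying an edge.
#' @export
graph_density <- function(g) {
  W <- as_adjacency(g)
  n <- nrow(W)
  if (n < 2) return(0)
  sum(W > 0) / (n * (n - 1))
}

#' @export
print.weighted_digraph <- function(x, ...) {
  cat(sprintf("weighted digraph: %d nodes, %d edges (density %.3f)\n",
              x$n_nodes, n_edges(x), graph_density(x)))
  w <- x$W[x$W > 0]
  if (length(w)) cat(sprintf("  weights in [%.4g, %.4g]\n", min(w), max(w)))
  invisible(x)
}

#' @export
print.binary_digraph <- function(x, ...) {
  cat(sprintf("binary digraph: %d nodes, %d edges (density %.3f)\n",
              x$n_nodes, n_edges(x), graph_density(x)))
  invisible(x)
}

#' Write a graph as a dense adjacency CSV
#'
#' One row per source node, columns named by target node ids.
#' @param g graph object.
#' @param path output file path.
#' @export
write_adjacency_csv <- function(g, path) {
  W <- as_adjacency(g)
  ids <- if (inherits(g, "weighted_digraph") || inherits(g, "binary_digraph"))
    g$node_ids else as.character(seq_len(nrow(W)))
  df <- as.data.frame(W)
  names(df) <- ids
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a dense adjacency CSV written by [write_adjacency_csv()]
#' @param path file path.
#' @param binary interpret entries as 0/1?
#' @return a `weighted_digraph` (or `binary_digraph` when `binary = TRUE`).
#' @export
read_adjacency_csv <- function(path, binary = FALSE) {
  df <- read.csv(path, check.names = FALSE)
  W <- as.matrix(df)
  if (binary) binary_digraph(W, node_ids = names(df))
  else weighted_digraph(W, node_ids = names(df))
}

#' Write a weighted graph as a 3-column edge list TSV (source, target, weight)
#' @param g a `weighted_digraph`.
#' @param path output file path.
#' @export
write_edgelist_tsv <- function(g, path) {
  W <- as_adjacency(g)
  idx <- which(W > 0, arr.ind = TRUE)
  df <- data.frame(source = idx[, 1], target = idx[, 2], weight = W[idx])
  df <- df[order(df$source, df$target), , drop = FALSE]
  write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an edge-list TSV into a weighted digraph
#' @param path file path with columns source, target, weight (1-based indices).
#' @param n_nodes total node count (needed because isolated nodes carry no rows).
#' @return a `weighted_digraph`.
#' @export
read_edgelist_tsv <- function(path, n_nodes) {
  df <- read.delim(path)
  W <- matrix(0, n_nodes, n_nodes)
  W[cbind(df$source, df$target)] <- df$weight
  weighted_digraph(W)
}
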