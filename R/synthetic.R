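#' Generate a random weighted digraph with a target edge density
#'
#' Every ordered off-diagonal pair carries an edge independently with
#' probability `density`; edge weights are drawn uniformly on (0, 1]. This is
#' the elementary subject model for the synthetic cohorts: nodes stand for
#' regions of interest (ROIs), edges for directed functional links.
#'
#' @param n_nodes number of nodes (default 96, the atlas size).
#' @param density expected fraction of ordered pairs carrying an edge, in (0, 1].
#' @param seed optional integer seed; when given, `set.seed(seed)` is called so
#'   the graph is fully reproducible.
#' @return a [weighted_digraph()].
#' @examples
#' g <- generate_random_digraph(10, 0.3, seed = 1)
#' graph_density(g)
#' @export
generate_random_digraph <- function(n_nodes = 96, density, seed = NULL) {
  if (!is.numeric(density) || length(density) != 1 || density <= 0 || density > 1)
    stop("density must lie in (0, 1]")
  if (n_nodes < 2) stop("need at least 2 nodes")
  if (!is.null(seed)) set.seed(seed)
  n <- n_nodes
  W <- matrix(0, n, n)
  off <- which(row(W) != col(W))
  present <- runif(length(off)) < density
  # 1 - runif() lies in (0, 1]: no zero-weight "present" edges
  W[off[present]] <- 1 - runif(sum(present))
  weighted_digraph(W)
}

#' Generate a mixed-density cohort of random digraphs
#'
#' Emulates a cohort of subjects whose brain networks differ only in overall
#' connection density: per subject a density is drawn uniformly in
#' `density_range` and a random digraph of that density is generated. Sparser
#' graphs play the role of progressively disconnected (diseased) brains,
#' denser graphs the role of healthy ones.
#'
#' @param n_subjects number of subjects (graphs).
#' @param n_nodes nodes per graph (default 96).
#' @param density_range length-2 numeric, low and high end of the uniform
#'   density draw; must satisfy 0 <= low <= high <= 1.
#' @param seed integer seed for the whole cohort.
#' @return list of subjects, each a list with `subject_id`, `graph`
#'   (a `weighted_digraph`) and `density` (the drawn target density).
#' @export
generate_cohort <- function(n_subjects, n_nodes = 96,
                            density_range = c(0, 1), seed = NULL) {
  if (length(density_range) != 2 || density_range[1] > density_range[2] ||
      density_range[1] < 0 || density_range[2] > 1)
    stop("density_range must be an increasing pair within [0, 1]")
  if (n_subjects < 0) stop("n_subjects must be nonnegative")
  if (!is.null(seed)) set.seed(seed)
  if (n_subjects == 0) return(list())
  dens <- runif(n_subjects, density_range[1], density_range[2])
  dens[dens <= 0] <- .Machine$double.eps # open interval at 0
  lapply(seq_len(n_subjects), function(i) {
    list(subject_id = sprintf("S%04d", i),
         graph = generate_random_digraph(n_nodes, dens[i]),
         density = dens[i])
  })
}

#' Generate a labeled two-class cohort with planted hemispheric asymmetry
#'
#' "healthy" subjects are denser random digraphs with statistically
#' exchangeable hemispheres; "affected" subjects are sparser, and the weights
#' incident to the right-hemisphere node of each designated left/right pair
#' are imbalanced: incoming weights scaled by `1 + asymmetry_strength`,
#' outgoing weights by `1 - asymmetry_strength`. This plants an
#' in-degree/out-degree imbalance concentrated in `affected_pairs`, mimicking
#' a disease that both disconnects the brain and breaks left-right symmetry.
#'
#' @param n_per_class subjects per class.
#' @param n_nodes nodes per graph; must be even (left hemisphere = first half,
#'   right = second half).
#' @param affected_pairs list of length-2 integer vectors `c(left, right)` of
#'   node indices receiving the planted asymmetry. Defaults to the two
#'   parahippocampal pairs of the default atlas, `(34, 82)` and `(35, 83)`.
#' @param asymmetry_strength nonnegative multiplicative imbalance; 0 yields
#'   exchangeable hemispheres. Must be < 1 so outgoing weights stay positive.
#' @param density_healthy,density_affected edge densities of the two classes;
#'   `density_affected` must not exceed `density_healthy` (disease is modeled
#'   as progressive disconnection). The defaults mirror the sparsity of the
#'   k = 15 out-kNN connectivity graphs the pipeline operates on
#'   (15 / 95 of ordered pairs, about 0.16), with the affected class thinned.
#' @param class_labels length-2 character, names of the healthy and affected
#'   groups.
#' @param seed integer seed.
#' @return list of subjects, each a list with `subject_id`, `graph`, `label`.
#' @export
generate_two_class_cohort <- function(n_per_class = 40, n_nodes = 96,
                                      affected_pairs = list(c(34, 82), c(35, 83)),
                                      asymmetry_strength = 0.6,
                                      density_healthy = 0.15,
                                      density_affected = 0.10,
                                      class_labels = c("healthy", "affected"),
                                      seed = NULL) {
  if (n_nodes %% 2 != 0) stop("n_nodes must be even for hemispheric pairing")
  if (density_affected > density_healthy)
    stop("density_affected must not exceed density_healthy")
  if (asymmetry_strength < 0 || asymmetry_strength >= 1)
    stop("asymmetry_strength must lie in [0, 1)")
  for (p in affected_pairs) {
    if (length(p) != 2 || p[1] == p[2]) stop("each pair needs two distinct indices")
    if (any(p < 1) || any(p > n_nodes)) stop("pair indices out of node range")
    if (p[1] > n_nodes / 2 || p[2] <= n_nodes / 2)
      stop("pairs must be (left-half index, right-half index)")
  }
  if (!is.null(seed)) set.seed(seed)
  subjects <- vector("list", 2 * n_per_class)
  idx <- 0
  for (cls in 1:2) {
    dens <- if (cls == 1) density_healthy else density_affected
    for (i in seq_len(n_per_class)) {
      g <- generate_random_digraph(n_nodes, dens)
      if (cls == 2 && asymmetry_strength > 0) {
        W <- g$W
        for (p in affected_pairs) {
          r <- p[2]
          W[, r] <- W[, r] * (1 + asymmetry_strength) # incoming boosted
          W[r, ] <- W[r, ] * (1 - asymmetry_strength) # outgoing weakened
        }
        g <- weighted_digraph(W, node_ids = g$node_ids)
      }
      idx <- idx + 1
      subjects[[idx]] <- list(subject_id = sprintf("%s%03d",
                                                   toupper(substr(class_labels[cls], 1, 1)), i),
                              graph = g, label = class_labels[cls])
    }
  }
  subjects
}

#' Generate BOLD-like multivariate time series with planted lag couplings
#'
#' Produces one Gaussian series per node. For each coupled pair `(from, to,
#' lag)` in `lag_map`, the target series is a copy of the source shifted by
#' `lag` samples plus independent Gaussian observation noise, so that the
#' time-lagged cross-correlation points from the leading to the lagging
#' region. Uncoupled nodes are independent white noise.
#'
#' The default series length, 130, mirrors a standard resting-state
#' acquisition of 140 volumes with the first 10 discarded for scanner
#' equilibration.
#'
#' @param n_nodes number of ROIs.
#' @param n_timepoints samples per series (default 130).
#' @param lag_map data frame with integer columns `from`, `to`, `lag`
#'   (positive lag: `from` leads `to`). Each node may be the target of at
#'   most one coupling. All |lag| must be below `n_timepoints / 4`.
#' @param noise_sd standard deviation of the additive noise on coupled
#'   targets (sources have unit-variance signal).
#' @param seed integer seed.
#' @return a `timeseries_set`: list with `series` (timepoints x nodes matrix),
#'   `roi_names`, `subject_id`.
#' @export
generate_bold_timeseries <- function(n_nodes, n_timepoints = 130,
                                     lag_map = NULL, noise_sd = 0.5,
                                     seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(lag_map))
    lag_map <- data.frame(from = integer(), to = integer(), lag = integer())
  if (nrow(lag_map)) {
    if (any(abs(lag_map$lag) >= n_timepoints / 4))
      stop("all |lag| must be below n_timepoints / 4")
    if (anyDuplicated(lag_map$to))
      stop("each node may be the target of at most one coupling")
    if (any(lag_map$from < 1 | lag_map$from > n_nodes |
            lag_map$to < 1 | lag_map$to > n_nodes))
      stop("lag_map node indices out of range")
    if (any(lag_map$from == lag_map$to)) stop("self-couplings are not allowed")
  }
  maxlag <- if (nrow(lag_map)) max(abs(lag_map$lag)) else 0
  buf_len <- n_timepoints + 2 * maxlag
  X <- matrix(rnorm(buf_len * n_nodes), buf_len, n_nodes)
  off <- maxlag # window start offset so shifts stay in-buffer
  S <- X[(off + 1):(off + n_timepoints), , drop = FALSE]
  for (r in seq_len(nrow(lag_map))) {
    i <- lag_map$from[r]; j <- lag_map$to[r]; L <- lag_map$lag[r]
    # y(t) = x(t - L): positive L means the source leads
    src <- X[(off + 1 - L):(off + n_timepoints - L), i]
    S[, j] <- src + if (noise_sd > 0) rnorm(n_timepoints, sd = noise_sd) else 0
  }
  structure(list(series = S,
                 roi_names = sprintf("ROI%02d", seq_len(n_nodes)),
                 subject_id = "synthetic"),
            class = "timeseries_set")
}

#' Write a cohort to disk (one adjacency CSV per subject plus a manifest TSV)
#'
#' @param cohort list of subjects from [generate_cohort()] or
#'   [generate_two_class_cohort()].
#' @param dir output directory (created if missing).
#' @return path of the manifest TSV, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  rows <- lapply(cohort, function(s) {
    path <- file.path(dir, paste0(s$subject_id, ".csv"))
    write_adjacency_csv(s$graph, path)
    data.frame(subject_id = s$subject_id,
               label = if (is.null(s$label)) NA_character_ else s$label,
               density = if (is.null(s$density)) graph_density(s$graph) else s$density,
               path = path)
  })
  manifest <- do.call(rbind, rows)
  mpath <- file.path(dir, "manifest.tsv")
  write.table(manifest, mpath, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(mpath)
}

#' Write a time-series set as CSV (rows = timepoints, columns = ROI names)
#' @param ts a `timeseries_set`.
#' @param path output file.
#' @export
write_timeseries_csv <- function(ts, path) {
  df <- as.data.frame(ts$series)
  names(df) <- ts$roi_names
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a time-series CSV (header = ROI names) into a `timeseries_set`
#' @param path file path.
#' @param subject_id subject identifier to attach.
#' @param group_label optional group label.
#' @export
read_timeseries_csv <- function(path, subject_id = basename(path),
                                group_label = NULL) {
  df <- read.csv(path, check.names = FALSE)
  keep <- !vapply(df, function(col) all(is.na(col)), logical(1))
  if (!all(keep))
    warning(sprintf("discarding %d ROI(s) with entirely missing series", sum(!keep)))
  df <- df[, keep, drop = FALSE]
  structure(list(series = as.matrix(df), roi_names = names(df),
                 subject_id = subject_id, group_label = group_label),
            class = "timeseries_set")
}
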