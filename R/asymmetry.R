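#' Default 96-ROI atlas with left-right hemispheric pairing
#'
#' Nodes 1-48 form the left hemisphere, nodes 49-96 the right; region `i`
#' pairs with region `i + 48`. Six anatomically named pairs (the fusiform,
#' parahippocampal and Heschl's regions with their Brodmann areas) are
#' hard-coded; the remaining 42 pairs carry placeholder names and can be
#' overridden with a user atlas ([read_atlas_tsv()]).
#'
#' @param n_nodes atlas size, must be even (default 96).
#' @return an object of class `roi_atlas`: list with `entries` (data frame:
#'   index, name, hemisphere, pair_index, brodmann) and `pairs` (data frame:
#'   left, right, region_name).
#' @export
default_roi_atlas <- function(n_nodes = 96) {
  if (n_nodes %% 2 != 0) stop("n_nodes must be even")
  half <- n_nodes / 2
  named <- data.frame(
    left = c(37, 34, 40, 39, 45, 35),
    name = c("Temporal Fusiform Cortex, anterior division",
             "Parahippocampal Gyrus, anterior division",
             "Occipital Fusiform Gyrus",
             "Temporal Occipital Fusiform Cortex",
             "Heschl's Gyrus (includes H1 and H2)",
             "Parahippocampal Gyrus, posterior division"),
    brodmann = c(36, 36, 19, 37, 48, 30))
  region_names <- sprintf("Region %02d", seq_len(half))
  brodmann <- rep(NA_integer_, half)
  keep <- named$left <= half
  region_names[named$left[keep]] <- named$name[keep]
  brodmann[named$left[keep]] <- named$brodmann[keep]
  entries <- data.frame(
    index = seq_len(n_nodes),
    name = c(paste0(region_names, " (L)"), paste0(region_names, " (R)")),
    hemisphere = rep(c("left", "right"), each = half),
    pair_index = c(seq_len(half) + half, seq_len(half)),
    brodmann = rep(brodmann, 2))
  pairs <- data.frame(left = seq_len(half), right = seq_len(half) + half,
                      region_name = region_names)
  structure(list(entries = entries, pairs = pairs, n_nodes = n_nodes),
            class = "roi_atlas")
}

#' @export
print.roi_atlas <- function(x, ...) {
  cat(sprintf("ROI atlas: %d nodes, %d left-right pairs\n",
              x$n_nodes, nrow(x$pairs)))
  invisible(x)
}

#' Write an ROI atlas as TSV (index, name, hemisphere, pair_index, brodmann)
#' @param atlas an `roi_atlas`.
#' @param path output file.
#' @export
write_atlas_tsv <- function(atlas, path) {
  write.table(atlas$entries, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an ROI atlas from TSV
#' @param path file with columns index, name, hemisphere, pair_index, brodmann.
#' @return an `roi_atlas`.
#' @export
read_atlas_tsv <- function(path) {
  e <- read.delim(path)
  lefts <- e[e$hemisphere == "left", ]
  pairs <- data.frame(left = lefts$index, right = lefts$pair_index,
                      region_name = sub(" \\(L\\)$", "", lefts$name))
  bad <- e$hemisphere[pairs$right] == e$hemisphere[pairs$left]
  if (any(bad)) stop("paired indices must have opposite hemispheres")
  structure(list(entries = e, pairs = pairs, n_nodes = nrow(e)),
            class = "roi_atlas")
}

#' In- and out-degrees of a binary digraph
#'
#' `d_in(u)` counts edges ending at `u` (column sums of the adjacency),
#' `d_out(u)` edges leaving `u` (row sums). Their totals both equal the edge
#' count, so in-out imbalance can only concentrate, never inflate globally.
#'
#' @param A a [binary_digraph()] (or 0/1 matrix).
#' @param subject_id optional subject identifier.
#' @return a `degree_profile`: list with `d_in`, `d_out`, `subject_id`.
#' @export
degree_profile <- function(A, subject_id = NULL) {
  M <- as_adjacency(A)
  structure(list(d_in = colSums(M), d_out = rowSums(M),
                 subject_id = subject_id),
            class = "degree_profile")
}

#' In-out-degree asymmetry of a node
#'
#' The difference `d_in(node) - d_out(node)`; positive for net receivers,
#' negative for net senders, 0 for isolated or balanced nodes. The ratio
#' form `(d_in + 1) / (d_out + 1)` (add-one smoothed, since the raw ratio is
#' undefined at `d_out = 0`) is available via `form = "ratio"`.
#'
#' @param profile a [degree_profile()].
#' @param node node index or vector of indices; defaults to all nodes.
#' @param form `"difference"` (default) or `"ratio"`.
#' @return numeric vector of asymmetry values.
#' @export
in_out_degree <- function(profile, node = seq_along(profile$d_in),
                          form = c("difference", "ratio")) {
  form <- match.arg(form)
  if (any(node < 1 | node > length(profile$d_in))) stop("node out of range")
  if (form == "difference") profile$d_in[node] - profile$d_out[node]
  else (profile$d_in[node] + 1) / (profile$d_out[node] + 1)
}

#' Rank nodes by in-out-degree difference, per subject
#'
#' Per subject, nodes are sorted in ascending order of `d_in - d_out` and
#' assigned ranks `n` down to 1 in that order (the most negative difference
#' gets rank `n`). Ties are broken by node index ascending.
#'
#' @param profiles list of [degree_profile()]s with a common node count.
#' @return numeric matrix, subjects x nodes, each row a permutation of
#'   `1..n`.
#' @export
rank_nodes <- function(profiles) {
  n <- length(profiles[[1]]$d_in)
  out <- matrix(0, length(profiles), n)
  for (s in seq_along(profiles)) {
    if (length(profiles[[s]]$d_in) != n) stop("profiles must share a node count")
    diffs <- in_out_degree(profiles[[s]])
    ord <- order(diffs, seq_len(n))
    out[s, ord] <- seq(n, 1)
  }
  out
}

subject_pair_values <- function(profiles, atlas, use_ranks) {
  # per subject, the value of every node: rank or raw in-out difference
  if (use_ranks) rank_nodes(profiles)
  else do.call(rbind, lapply(profiles, in_out_degree))
}

#' Left-right hemispheric asymmetry per region pair and group
#'
#' For every atlas pair and every group, aggregates the subject-mean left
#' value, right value and their difference, where the per-node value is the
#' per-subject rank (default, ranks carry the comparison between regions) or
#' the raw in-out-degree difference.
#'
#' @param profiles list of [degree_profile()]s.
#' @param atlas an `roi_atlas`.
#' @param labels character vector of group labels, one per profile; a single
#'   value is recycled.
#' @param use_ranks aggregate per-subject node ranks (default) instead of raw
#'   differences.
#' @return data frame of class `asymmetry_records` with columns
#'   `region_name`, `group_label`, `left_value`, `right_value`,
#'   `pair_difference` (= left - right).
#' @export
hemispheric_asymmetry <- function(profiles, atlas = default_roi_atlas(),
                                  labels = "all", use_ranks = TRUE) {
  n <- length(profiles[[1]]$d_in)
  ok <- atlas$pairs$left <= n & atlas$pairs$right <= n
  if (!all(ok)) {
    warning(sprintf("skipping %d atlas pair(s) outside the node range", sum(!ok)))
  }
  pairs <- atlas$pairs[ok, , drop = FALSE]
  labels <- rep_len(labels, length(profiles))
  V <- subject_pair_values(profiles, atlas, use_ranks)
  out <- do.call(rbind, lapply(unique(labels), function(gl) {
    Vg <- V[labels == gl, , drop = FALSE]
    lv <- colMeans(Vg[, pairs$left, drop = FALSE])
    rv <- colMeans(Vg[, pairs$right, drop = FALSE])
    data.frame(region_name = pairs$region_name, group_label = gl,
               left_value = lv, right_value = rv,
               pair_difference = lv - rv, row.names = NULL)
  }))
  class(out) <- c("asymmetry_records", "data.frame")
  out
}

#' Most asymmetric regions between two groups
#'
#' Ranks regions by the absolute between-group difference of their left-right
#' `pair_difference` and returns the top `n_top` region names (ties broken by
#' region name).
#'
#' @param records an `asymmetry_records` data frame covering exactly two
#'   groups (see [hemispheric_asymmetry()]).
#' @param n_top how many regions to return (default 6).
#' @return character vector of region names.
#' @export
top_asymmetric_regions <- function(records, n_top = 6) {
  groups <- unique(records$group_label)
  if (length(groups) != 2) stop("records must cover exactly two groups")
  a <- records[records$group_label == groups[1], ]
  b <- records[records$group_label == groups[2], ]
  b <- b[match(a$region_name, b$region_name), ]
  between <- abs(a$pair_difference - b$pair_difference)
  ord <- order(-between, a$region_name)
  if (n_top > length(ord)) {
    warning("n_top exceeds the number of regions: returning all")
    n_top <- length(ord)
  }
  a$region_name[ord][seq_len(n_top)]
}

#' Two-sided Mann-Whitney U comparison of two samples
#'
#' Normal approximation with continuity correction; all-identical pooled
#' values give `p = 1` by convention.
#'
#' @param a,b numeric samples (e.g. per-subject left-right differences of one
#'   region in each group).
#' @return two-sided p-value.
#' @export
group_compare <- function(a, b) {
  if (!length(a) || !length(b)) stop("both samples must be nonempty")
  if (length(unique(c(a, b))) == 1) return(1)
  suppressWarnings(
    wilcox.test(a, b, exact = FALSE, correct = TRUE)$p.value)
}

#' Per-region group comparison table
#'
#' For every atlas pair, compares the per-subject left-right asymmetry values
#' between the two groups with the Mann-Whitney U test. Raw p-values are
#' reported alongside a Benjamini-Hochberg adjusted column (the adjustment is
#' an extension beyond the raw pairwise comparisons).
#'
#' @inheritParams hemispheric_asymmetry
#' @return data frame with columns `region_name`, per-group means of left,
#'   right and difference, `p_value` and `p_adjusted`.
#' @export
region_group_tests <- function(profiles, atlas = default_roi_atlas(), labels,
                               use_ranks = TRUE) {
  groups <- unique(labels)
  if (length(groups) != 2) stop("exactly two groups are required")
  n <- length(profiles[[1]]$d_in)
  pairs <- atlas$pairs[atlas$pairs$left <= n & atlas$pairs$right <= n, ]
  V <- subject_pair_values(profiles, atlas, use_ranks)
  D <- V[, pairs$left, drop = FALSE] - V[, pairs$right, drop = FALSE]
  p <- vapply(seq_len(ncol(D)), function(r)
    group_compare(D[labels == groups[1], r], D[labels == groups[2], r]),
    numeric(1))
  data.frame(region_name = pairs$region_name,
             mean_diff_group1 = colMeans(D[labels == groups[1], , drop = FALSE]),
             mean_diff_group2 = colMeans(D[labels == groups[2], , drop = FALSE]),
             p_value = p,
             p_adjusted = p.adjust(p, method = "BH"),
             row.names = NULL)
}
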