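#' Per-subject feature vectors from selected region pairs
#'
#' For each selected region (in the order given) the four degrees of its
#' left and right nodes are concatenated: `(d_in_left, d_out_left,
#' d_in_right, d_out_right)`, giving `4 * length(regions)` features per
#' subject (24 for the default six regions).
#'
#' @param profiles list of [degree_profile()]s.
#' @param regions character vector of region names (e.g. from
#'   [top_asymmetric_regions()]).
#' @param atlas an `roi_atlas` resolving region names to node pairs.
#' @param labels group label per profile.
#' @return a `feature_set`: list with `x` (subjects x features matrix),
#'   `labels`, `feature_names`, `subject_ids`.
#' @export
build_features <- function(profiles, regions, atlas = default_roi_atlas(),
                           labels = NULL) {
  hit <- match(regions, atlas$pairs$region_name)
  if (anyNA(hit))
    stop("regions not in atlas: ", paste(regions[is.na(hit)], collapse = ", "))
  lefts <- atlas$pairs$left[hit]
  rights <- atlas$pairs$right[hit]
  n <- length(profiles[[1]]$d_in)
  bad <- lefts > n | rights > n
  if (any(bad))
    stop(sprintf("region '%s' maps to a node beyond the %d-node profiles",
                 regions[which(bad)[1]], n))
  X <- t(vapply(profiles, function(p) {
    as.vector(rbind(p$d_in[lefts], p$d_out[lefts],
                    p$d_in[rights], p$d_out[rights]))
  }, numeric(4 * length(regions))))
  feature_names <- as.vector(vapply(regions, function(r)
    paste0(r, c("_in_L", "_out_L", "_in_R", "_out_R")), character(4)))
  colnames(X) <- feature_names
  structure(list(x = X,
                 labels = labels,
                 feature_names = feature_names,
                 subject_ids = vapply(profiles, function(p)
                   if (is.null(p$subject_id)) NA_character_ else p$subject_id,
                   character(1))),
            class = "feature_set")
}

# Pooled-covariance (Fisher) linear discriminant for two classes, with ridge
# escalation when the pooled covariance is singular (common with small folds
# and 24 integer-degree features). Deterministic by construction.
fisher_lda_fit <- function(X, y) {
  classes <- sort(unique(y))
  if (length(classes) != 2) stop("exactly two classes are required")
  X0 <- X[y == classes[1], , drop = FALSE]
  X1 <- X[y == classes[2], , drop = FALSE]
  m0 <- colMeans(X0); m1 <- colMeans(X1)
  n <- nrow(X)
  S <- (crossprod(sweep(X0, 2, m0)) + crossprod(sweep(X1, 2, m1))) / (n - 2)
  scale <- mean(diag(S))
  if (scale <= 0) scale <- 1
  lambda <- 0
  repeat {
    Sr <- S + diag(lambda * scale, ncol(S))
    w <- tryCatch(solve(Sr, m1 - m0), error = function(e) NULL)
    if (!is.null(w) && all(is.finite(w))) break
    lambda <- if (lambda == 0) 1e-6 else lambda * 10
    if (lambda > 1) stop("pooled covariance irreparably singular")
  }
  prior0 <- nrow(X0) / n; prior1 <- nrow(X1) / n
  cut <- sum(w * (m0 + m1)) / 2 - log(prior1 / prior0)
  list(w = w, cut = cut, classes = classes)
}

fisher_lda_predict <- function(fit, X) {
  score <- as.vector(X %*% fit$w)
  ifelse(score > fit$cut, fit$classes[2], fit$classes[1])
}

# Stratified fold assignment: within each class, subjects are shuffled and
# dealt round-robin, so every fold holds both classes whenever each class has
# at least n_folds members.
stratified_folds <- function(labels, n_folds, seed) {
  set.seed(seed)
  fold <- integer(length(labels))
  for (cls in unique(labels)) {
    idx <- which(labels == cls)
    idx <- idx[sample.int(length(idx))]
    fold[idx] <- rep_len(seq_len(n_folds), length(idx))
  }
  fold
}

#' Cross-validated linear discriminant classification
#'
#' Stratified random partition into `n_folds` disjoint folds; per fold a
#' pooled-covariance LDA is trained on the remaining folds and evaluated on
#' the held-out one. Accuracy is the mean of the fold accuracies (with its
#' across-fold standard deviation); sensitivity, specificity and precision
#' are computed from the pooled confusion matrix with the affected group as
#' the positive class. All metrics are percentages.
#'
#' @param features a `feature_set` from [build_features()] (with labels), or
#'   a list with `x` and `labels`.
#' @param n_folds number of folds (default 10).
#' @param seed integer seed for the fold assignment.
#' @param positive name of the positive (affected) class; defaults to
#'   `"affected"` when present, otherwise the second sorted label.
#' @param folds optional precomputed fold assignment (overrides `seed`), used
#'   to share folds across pipeline arms.
#' @return a `cv_result`: list with `accuracy`, `accuracy_sd`, `sensitivity`,
#'   `specificity`, `precision`, `fold_accuracies`, `confusion`, `folds`,
#'   `seed`.
#' @export
lda_cross_validate <- function(features, n_folds = 10, seed = 1,
                               positive = NULL, folds = NULL) {
  X <- features$x
  y <- features$labels
  if (is.null(y)) stop("features must carry group labels")
  classes <- sort(unique(y))
  if (length(classes) != 2) stop("exactly two classes are required")
  if (min(table(y)) < n_folds)
    stop("each class needs at least n_folds subjects for stratified folds")
  if (is.null(positive))
    positive <- if ("affected" %in% classes) "affected" else classes[2]
  negative <- setdiff(classes, positive)
  if (is.null(folds)) {
    s <- seed
    repeat {
      folds <- stratified_folds(y, n_folds, s)
      complete <- all(vapply(seq_len(n_folds), function(f)
        length(unique(y[folds == f])) == 2, logical(1)))
      if (complete) break
      warning("a fold missed a class: re-partitioning with the next seed")
      s <- s + 1
    }
  }
  fold_acc <- numeric(n_folds)
  conf <- matrix(0, 2, 2, dimnames = list(truth = c(positive, negative),
                                          pred = c(positive, negative)))
  for (f in seq_len(n_folds)) {
    test <- folds == f
    fit <- fisher_lda_fit(X[!test, , drop = FALSE], y[!test])
    pred <- fisher_lda_predict(fit, X[test, , drop = FALSE])
    fold_acc[f] <- mean(pred == y[test])
    for (cls_t in c(positive, negative)) for (cls_p in c(positive, negative))
      conf[cls_t, cls_p] <- conf[cls_t, cls_p] +
        sum(y[test] == cls_t & pred == cls_p)
  }
  tp <- conf[positive, positive]; fn <- conf[positive, negative]
  tn <- conf[negative, negative]; fp <- conf[negative, positive]
  structure(list(
    accuracy = 100 * mean(fold_acc),
    accuracy_sd = 100 * sd(fold_acc),
    sensitivity = 100 * tp / max(tp + fn, 1),
    specificity = 100 * tn / max(tn + fp, 1),
    precision = 100 * tp / max(tp + fp, 1),
    fold_accuracies = 100 * fold_acc,
    confusion = conf, folds = folds, positive = positive, seed = seed),
    class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("LDA %d-fold cross-validation (positive class: %s)\n",
              length(x$fold_accuracies), x$positive))
  cat(sprintf("  accuracy    %.2f%% (+/- %.2f)\n", x$accuracy, x$accuracy_sd))
  cat(sprintf("  sensitivity %.2f%%  specificity %.2f%%  precision %.2f%%\n",
              x$sensitivity, x$specificity, x$precision))
  invisible(x)
}

#' Compare the RRW-filtered and non-filtered classification arms
#'
#' Runs the degree-asymmetry classification pipeline twice on the same
#' labeled cohort — once on the raw thresholded graphs, once on the
#' RRW-filtered (`We''`) thresholded graphs — with identical fold
#' assignments, and returns both cross-validation results. Region selection
#' (the most asymmetric pairs) is redone per arm, as each arm sees different
#' graphs.
#'
#' @param cohort labeled cohort from [generate_two_class_cohort()] (or any
#'   list of `list(subject_id, graph, label)`).
#' @param atlas an `roi_atlas`.
#' @param c_threshold top-fraction retained when binarizing (default 0.40).
#' @param n_top number of most-asymmetric regions fed to the classifier
#'   (default 6).
#' @param n_folds,seed cross-validation controls (folds shared across arms).
#' @param use_ranks rank-based region selection (default TRUE).
#' @return a `pipeline_comparison`: list with `with_rrw`, `without_rrw`
#'   (both `cv_result`), `accuracy_difference`, `regions_with_rrw`,
#'   `regions_without_rrw`.
#' @export
compare_pipelines <- function(cohort, atlas = default_roi_atlas(),
                              c_threshold = 0.40, n_top = 6, n_folds = 10,
                              seed = 1, use_ranks = TRUE) {
  labels <- vapply(cohort, `[[`, character(1), "label")
  folds <- NULL
  arm <- function(use_rrw) {
    profiles <- lapply(cohort, function(s) {
      g <- if (use_rrw)
        weighted_digraph(apply_directed_rrw(s$graph)$We_dprime)
      else s$graph
      degree_profile(threshold_top_c(g, c_threshold), s$subject_id)
    })
    rec <- hemispheric_asymmetry(profiles, atlas, labels, use_ranks)
    regions <- top_asymmetric_regions(rec, n_top)
    feats <- build_features(profiles, regions, atlas, labels)
    cv <- lda_cross_validate(feats, n_folds, seed, folds = folds)
    list(cv = cv, regions = regions)
  }
  rrw_arm <- arm(TRUE)
  folds <- rrw_arm$cv$folds # reuse exact fold assignment in the second arm
  raw_arm <- arm(FALSE)
  structure(list(with_rrw = rrw_arm$cv, without_rrw = raw_arm$cv,
                 accuracy_difference = rrw_arm$cv$accuracy - raw_arm$cv$accuracy,
                 regions_with_rrw = rrw_arm$regions,
                 regions_without_rrw = raw_arm$regions),
            class = "pipeline_comparison")
}

#' @export
print.pipeline_comparison <- function(x, ...) {
  cat("pipeline comparison (identical folds)\n")
  cat(sprintf("  with RRW:    %.2f%% accuracy\n", x$with_rrw$accuracy))
  cat(sprintf("  non-filtered: %.2f%% accuracy\n", x$without_rrw$accuracy))
  cat(sprintf("  difference:  %+.2f points\n", x$accuracy_difference))
  invisible(x)
}
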