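#' Derive a reproducible per-stage seed from a global seed
#'
#' Stage seeds are a fixed hash of the global seed and the stage name
#' (`(seed * 7919 + weighted character sum) mod (2^31 - 1)`), so every stage
#' is independently reproducible from the single global seed.
#'
#' @param global_seed integer global seed.
#' @param stage stage name string.
#' @return integer seed.
#' @export
stage_seed <- function(global_seed, stage) {
  chars <- utf8ToInt(stage)
  h <- sum(chars * seq_along(chars)) %% 104729
  as.integer((as.numeric(global_seed) * 7919 + h) %% 2147483647)
}

#' Pipeline configuration
#'
#' Bundles the stage toggles and stage parameters of [run_pipeline()].
#'
#' @param use_net4lap precondition each graph with [precondition()] before
#'   the RRW filter (mainly useful when graphs come from noisy correlation
#'   estimates; synthetic adjacency cohorts are usually run without it).
#' @param use_rrw apply the directed Return Random Walk filter.
#' @param c_threshold top-fraction retained at binarization (default 0.40).
#' @param knn_k kNN size for graph construction/preconditioning (default 15).
#' @param n_top number of most-asymmetric region pairs used as classifier
#'   features (default 6).
#' @param n_folds cross-validation folds (default 10).
#' @param seed global seed, fanned out per stage via [stage_seed()].
#' @param synth arguments passed to [generate_two_class_cohort()] when no
#'   cohort is supplied to [run_pipeline()].
#' @param embedding an [embedding_config()] for the preconditioning stage.
#' @param regularization a [regularization_config()].
#' @param use_ranks rank-based aggregation in the asymmetry stage.
#' @return a list of class `pipeline_config`.
#' @export
pipeline_config <- function(use_net4lap = FALSE, use_rrw = TRUE,
                            c_threshold = 0.40, knn_k = 15, n_top = 6,
                            n_folds = 10, seed = 1, synth = list(),
                            embedding = NULL, regularization = NULL,
                            use_ranks = TRUE) {
  if (c_threshold <= 0 || c_threshold > 1) stop("c_threshold must lie in (0, 1]")
  structure(list(use_net4lap = use_net4lap, use_rrw = use_rrw,
                 c_threshold = c_threshold, knn_k = knn_k, n_top = n_top,
                 n_folds = n_folds, seed = seed, synth = synth,
                 embedding = embedding, regularization = regularization,
                 use_ranks = use_ranks),
            class = "pipeline_config")
}

#' Run the end-to-end asymmetry pipeline
#'
#' Executes the enabled stages in order: cohort synthesis (or the supplied
#' cohort) -> optional net4Lap preconditioning -> optional directed RRW
#' filtering -> top-c binarization -> degree/asymmetry analysis -> LDA
#' cross-validation. Returns a manifest recording the configuration, stage
#' seeds, per-stage summaries and (when `output_dir` is given) the paths of
#' every written artifact.
#'
#' @param cfg a [pipeline_config()].
#' @param cohort optional labeled cohort (as from
#'   [generate_two_class_cohort()]); synthesized from `cfg$synth` when
#'   missing.
#' @param atlas an `roi_atlas`.
#' @param output_dir optional directory for intermediate artifacts
#'   (adjacency CSVs, asymmetry table, CV report).
#' @return a list of class `pipeline_run` with elements `config`, `seeds`,
#'   `stages` (per-stage summary stats), `asymmetry`, `regions`, `cv`,
#'   `files`.
#' @export
run_pipeline <- function(cfg = pipeline_config(), cohort = NULL,
                         atlas = default_roi_atlas(), output_dir = NULL) {
  seeds <- list(synth = stage_seed(cfg$seed, "synth"),
                net4lap = stage_seed(cfg$seed, "net4lap"),
                classify = stage_seed(cfg$seed, "classify"))
  files <- list()
  stages <- list()
  summarize <- function(graphs) {
    dens <- vapply(graphs, graph_density, numeric(1))
    list(n_graphs = length(graphs),
         mean_edges = mean(vapply(graphs, n_edges, numeric(1))),
         mean_density = mean(dens))
  }
  if (is.null(cohort)) {
    cohort <- do.call(generate_two_class_cohort,
                      c(cfg$synth, list(seed = seeds$synth)))
  }
  labels <- vapply(cohort, function(s)
    if (is.null(s$label)) "all" else s$label, character(1))
  graphs <- lapply(cohort, `[[`, "graph")
  stages$input <- summarize(graphs)

  if (cfg$use_net4lap) {
    ecfg <- if (is.null(cfg$embedding))
      embedding_config(knn_k = cfg$knn_k, seed = seeds$net4lap)
    else cfg$embedding
    rcfg <- if (is.null(cfg$regularization)) regularization_config()
    else cfg$regularization
    graphs <- lapply(graphs, precondition, ecfg = ecfg, rcfg = rcfg)
    stages$net4lap <- summarize(graphs)
  }
  if (cfg$use_rrw) {
    graphs <- lapply(graphs, function(g)
      weighted_digraph(apply_directed_rrw(g)$We_dprime))
    stages$rrw <- summarize(graphs)
  }
  binaries <- lapply(graphs, threshold_top_c, c = cfg$c_threshold)
  profiles <- Map(function(b, s) degree_profile(b, s$subject_id),
                  binaries, cohort)
  stages$threshold <- c(summarize(binaries),
                        list(mean_total_asymmetry = mean(vapply(profiles,
                          function(p) sum(abs(in_out_degree(p))), numeric(1)))))
  records <- hemispheric_asymmetry(profiles, atlas, labels, cfg$use_ranks)
  two_groups <- length(unique(labels)) == 2
  regions <- if (two_groups) top_asymmetric_regions(records, cfg$n_top) else NULL
  tests <- if (two_groups) region_group_tests(profiles, atlas, labels,
                                              cfg$use_ranks) else NULL
  cv <- NULL
  if (two_groups) {
    feats <- build_features(profiles, regions, atlas, labels)
    cv <- lda_cross_validate(feats, cfg$n_folds, seeds$classify)
  }
  if (!is.null(output_dir)) {
    if (!dir.exists(output_dir)) dir.create(output_dir, recursive = TRUE)
    gd <- file.path(output_dir, "graphs")
    files$cohort <- write_cohort(Map(function(s, g) {
      s$graph <- g; s
    }, cohort, graphs), gd)
    files$asymmetry <- file.path(output_dir, "asymmetry.csv")
    write.csv(records, files$asymmetry, row.names = FALSE)
    if (!is.null(tests)) {
      files$tests <- file.path(output_dir, "region_tests.csv")
      write.csv(tests, files$tests, row.names = FALSE)
    }
  }
  structure(list(config = cfg, seeds = seeds, stages = stages,
                 asymmetry = records, region_tests = tests,
                 regions = regions, cv = cv, files = files),
            class = "pipeline_run")
}

#' @export
print.pipeline_run <- function(x, ...) {
  cat("pipeline run\n")
  for (nm in names(x$stages)) {
    st <- x$stages[[nm]]
    cat(sprintf("  %-10s %d graphs, mean %.0f edges (density %.3f)\n",
                nm, st$n_graphs, st$mean_edges, st$mean_density))
  }
  if (!is.null(x$regions))
    cat("  top regions:", paste(x$regions, collapse = "; "), "\n")
  if (!is.null(x$cv))
    cat(sprintf("  LDA accuracy %.2f%% (+/- %.2f)\n",
                x$cv$accuracy, x$cv$accuracy_sd))
  invisible(x)
}

#' Threshold sweep over the sparsest subjects
#'
#' For the `n_subjects` sparsest cohort members, reports the total
#' in-out-degree asymmetry `sum_u |d_in(u) - d_out(u)|` per subject at each
#' binarization fraction `c`, and the `c` maximizing the mean total
#' asymmetry. Used to pick the working threshold (the default pipeline
#' threshold, 40%, is the maximizer on the reference synthetic cohort).
#'
#' @param cohort list of subjects with `graph` elements (densities taken
#'   from the stored `density` or recomputed).
#' @param c_values thresholds to scan (default 10, 25, 40, 50%).
#' @param n_subjects how many of the sparsest subjects to use (default 30;
#'   all, with a warning, when the cohort is smaller).
#' @param use_rrw sweep the RRW-filtered (`We''`) graphs (default) or the
#'   raw graphs.
#' @return list with `table` (data frame: subject_id, density, one column
#'   per `c`), `mean_total` (named mean asymmetry per `c`) and `best_c`.
#' @export
sweep_threshold <- function(cohort, c_values = c(0.10, 0.25, 0.40, 0.50),
                            n_subjects = 30, use_rrw = TRUE) {
  if (any(c_values <= 0 | c_values > 1)) stop("c_values must lie in (0, 1]")
  dens <- vapply(cohort, function(s)
    if (is.null(s$density)) graph_density(s$graph) else s$density, numeric(1))
  if (length(cohort) < n_subjects) {
    warning("cohort smaller than n_subjects: using all subjects")
    n_subjects <- length(cohort)
  }
  pick <- order(dens)[seq_len(n_subjects)]
  totals <- matrix(0, length(pick), length(c_values))
  for (z in seq_along(pick)) {
    g <- cohort[[pick[z]]]$graph
    if (use_rrw) g <- weighted_digraph(apply_directed_rrw(g)$We_dprime)
    totals[z, ] <- vapply(c_values, function(cc) {
      p <- degree_profile(threshold_top_c(g, cc))
      sum(abs(in_out_degree(p)))
    }, numeric(1))
  }
  colnames(totals) <- sprintf("c_%02d", round(100 * c_values))
  tab <- cbind(
    data.frame(subject_id = vapply(cohort[pick], `[[`, character(1),
                                   "subject_id"),
               density = dens[pick]),
    as.data.frame(totals))
  mean_total <- colMeans(totals)
  list(table = tab, mean_total = mean_total,
       best_c = c_values[which.max(mean_total)])
}
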