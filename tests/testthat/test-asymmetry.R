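test_that("the default atlas pairs left and right hemispheres correctly", {
  atlas <- default_roi_atlas()
  expect_equal(atlas$n_nodes, 96)
  expect_equal(nrow(atlas$pairs), 48)
  expect_true(all(atlas$pairs$right == atlas$pairs$left + 48))
  # the six named regions sit at their published indices
  named <- c("Parahippocampal Gyrus, anterior division" = 34,
             "Parahippocampal Gyrus, posterior division" = 35,
             "Temporal Fusiform Cortex, anterior division" = 37,
             "Temporal Occipital Fusiform Cortex" = 39,
             "Occipital Fusiform Gyrus" = 40,
             "Heschl's Gyrus (includes H1 and H2)" = 45)
  for (nm in names(named))
    expect_equal(atlas$pairs$left[atlas$pairs$region_name == nm],
                 unname(named[nm]))
  # round-trip through TSV
  p <- tempfile(fileext = ".tsv")
  write_atlas_tsv(atlas, p)
  atlas2 <- read_atlas_tsv(p)
  expect_equal(atlas2$pairs, atlas$pairs)
})

test_that("degree profiles count in and out edges and conserve totals", {
  A <- matrix(0, 3, 3); A[1, 2] <- 1
  p <- degree_profile(binary_digraph(A))
  expect_equal(p$d_out, c(1, 0, 0))
  expect_equal(p$d_in, c(0, 1, 0))

  # symmetric adjacency: d_in = d_out elementwise
  A <- matrix(0, 5, 5); A[2, 4] <- A[4, 2] <- 1; A[1, 5] <- A[5, 1] <- 1
  p <- degree_profile(binary_digraph(A))
  expect_equal(p$d_in, p$d_out)

  # conservation on random binary graphs
  set.seed(41)
  for (t in 1:100) {
    b <- threshold_top_c(generate_random_digraph(12, runif(1, 0.1, 0.9)), 0.5)
    p <- degree_profile(b)
    expect_equal(sum(p$d_in), n_edges(b))
    expect_equal(sum(p$d_out), n_edges(b))
    expect_equal(sum(in_out_degree(p)), 0)
  }
})

test_that("in-out-degree handles sinks, sources and the ratio form", {
  A <- matrix(0, 6, 6); A[1:5, 6] <- 1 # node 6 is a pure sink
  p <- degree_profile(binary_digraph(A))
  expect_equal(in_out_degree(p, 6), 5)
  expect_equal(in_out_degree(p, 1), -1)
  expect_equal(in_out_degree(degree_profile(binary_digraph(matrix(0, 3, 3))), 2), 0)
  expect_equal(in_out_degree(p, 6, form = "ratio"), 6 / 1)
  expect_error(in_out_degree(p, 9), "range")
})

test_that("node ranking sorts ascending differences to ranks n..1", {
  mk <- function(d_in, d_out)
    structure(list(d_in = d_in, d_out = d_out), class = "degree_profile")
  n <- 96
  prof <- degree_profile(threshold_top_c(
    generate_random_digraph(n, 0.5, seed = 42), 0.4))
  r <- rank_nodes(list(prof))[1, ]
  expect_setequal(r, 1:96) # a permutation of 1..96
  # the smallest difference gets the top rank
  expect_equal(r[order(in_out_degree(prof), seq_len(n))[1]], 96)

  # all-tied differences: ranks n, n-1, ... by node index
  prof0 <- mk(rep(2, 5), rep(2, 5))
  expect_equal(rank_nodes(list(prof0))[1, ], 5:1)

  # antisymmetry: negating all differences reverses the rank order (no ties)
  prof1 <- mk(c(5, 1, 3, 0), rep(0, 4))
  prof2 <- mk(rep(0, 4), c(5, 1, 3, 0))
  r1 <- rank_nodes(list(prof1))[1, ]
  r2 <- rank_nodes(list(prof2))[1, ]
  expect_equal(r2, 5 - r1)
})

test_that("hemispheric asymmetry is zero for symmetric graphs and recovers a planted pair", {
  atlas <- default_roi_atlas()
  # symmetric graphs: every raw in-out value is 0, so all pair differences are 0
  set.seed(43)
  profs <- replicate(10, {
    U <- matrix(runif(96 * 96) < 0.1, 96, 96)
    A <- (U | t(U)) + 0
    diag(A) <- 0
    degree_profile(binary_digraph(A))
  }, simplify = FALSE)
  rec <- hemispheric_asymmetry(profs, atlas, use_ranks = FALSE)
  expect_true(all(rec$pair_difference == 0))

  # asymmetry planted only in pair (34, 82): that pair dominates
  ch <- generate_two_class_cohort(n_per_class = 60,
                                  affected_pairs = list(c(34, 82)),
                                  asymmetry_strength = 0.7, seed = 44)
  profs <- lapply(ch, function(s) degree_profile(threshold_top_c(s$graph, 0.4)))
  labels <- vapply(ch, `[[`, character(1), "label")
  rec <- hemispheric_asymmetry(profs, atlas, labels)
  top <- top_asymmetric_regions(rec, 1)
  expect_equal(top, "Parahippocampal Gyrus, anterior division")

  # group averages invariant to subject order
  perm <- sample(length(profs))
  rec2 <- hemispheric_asymmetry(profs[perm], atlas, labels[perm])
  rec2 <- rec2[order(rec2$group_label, rec2$region_name), ]
  rec1 <- rec[order(rec$group_label, rec$region_name), ]
  expect_equal(rec1$pair_difference, rec2$pair_difference)
})

test_that("top regions break ties by name and warn when over-asked", {
  rec <- data.frame(region_name = rep(letters[1:5], 2),
                    group_label = rep(c("g1", "g2"), each = 5),
                    left_value = 0, right_value = 0,
                    pair_difference = 0)
  class(rec) <- c("asymmetry_records", "data.frame")
  expect_equal(top_asymmetric_regions(rec, 3), c("a", "b", "c"))
  expect_warning(out <- top_asymmetric_regions(rec, 9), "n_top")
  expect_length(out, 5)
})

test_that("Mann-Whitney comparison matches conventions and enumeration", {
  expect_equal(group_compare(c(1, 1, 1), c(1, 1)), 1) # identical pooled values

  # disjoint supports, n = 20 each: overwhelming evidence
  expect_lt(group_compare(1:20, 101:120), 1e-6)

  # U statistic matches exhaustive pair counting for small samples
  set.seed(45)
  for (t in 1:20) {
    x <- sample(1000, sample(3:8, 1))
    y <- sample(2000, sample(3:8, 1)) + 0.5
    U <- sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
    expect_equal(unname(suppressWarnings(
      wilcox.test(x, y, exact = FALSE)$statistic)), U)
  }
})

test_that("null cohorts reject at close to the nominal rate across pairs", {
  ch <- generate_two_class_cohort(n_per_class = 150, asymmetry_strength = 0,
                                  density_healthy = 0.25,
                                  density_affected = 0.25, seed = 46)
  profs <- lapply(ch, function(s) degree_profile(threshold_top_c(s$graph, 0.4)))
  labels <- vapply(ch, `[[`, character(1), "label")
  tests <- region_group_tests(profs, default_roi_atlas(), labels,
                              use_ranks = FALSE)
  expect_equal(nrow(tests), 48)
  # Binomial(48, 0.05) has mean 2.4, sd 1.51: 8+ rejections would be extreme
  expect_lte(sum(tests$p_value < 0.05), 8)
  expect_true(all(tests$p_adjusted >= tests$p_value))
})
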