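---
title: "Detecting hemispheric asymmetries in directed brain networks with return random walks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting hemispheric asymmetries in directed brain networks with return random walks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rrwasym)
```

## The problem

Resting-state fMRI measures a BOLD time series in each of 96 anatomically
labeled regions of interest (ROIs), 48 per hemisphere. Functional
connectivity between regions is usually summarized as an *undirected*
correlation graph, but directionality — which region's activity leads which —
carries information that undirected graphs discard. In particular, several
neurodegenerative conditions are believed to break the left–right symmetry
of regional connectivity early in their course, before whole-brain summary
statistics move. A directed graph lets us quantify that imbalance per node
as the difference between incoming and outgoing links.

The obstacle is noise: graphs inferred from lagged correlations of noisy
BOLD signals contain many spurious inter-cluster edges, and the in/out-degree
distributions of diseased and healthy subjects overlap almost completely.
This package implements a two-stage graph preconditioning and filtering
pipeline that amplifies genuine asymmetries while suppressing structural
noise, together with the synthetic-cohort generators needed to validate
every stage without any imaging data.

## Pipeline overview

1. **Graph construction** (`build_directed_graph`): for every pair of ROI
   series, the time-lagged cross-correlation is maximized over lags in
   `[-max_lag, max_lag]`; the pair contributes an edge of weight
   |correlation| directed from the leading to the lagging region (zero-lag
   pairs become bidirectional). Each node keeps its `k = 15` strongest
   outgoing candidates, giving a sparse directed kNN graph.
2. **Preconditioning** (`precondition`): the kNN graph is re-expressed
   through a neural node embedding and Laplacian-regularized ranking
   (details below), producing a graph that is locally more isotropic.
3. **Return-random-walk filtering** (`apply_directed_rrw`): every ordered
   pair is rescored by its best two-step go-and-return cycle, which
   reinforces intra-cluster links and suppresses inter-cluster noise.
4. **Binarization** (`threshold_top_c`): the top 40% of the filtered
   weights become a binary directed adjacency matrix.
5. **Asymmetry analysis** (`degree_profile`, `hemispheric_asymmetry`,
   `top_asymmetric_regions`): per-node in/out-degree differences are
   ranked per subject and compared between the paired left/right ROIs;
   the regions with the largest between-group left–right imbalance are
   selected.
6. **Classification** (`build_features`, `lda_cross_validate`,
   `compare_pipelines`): the four degrees of each selected region pair
   form a feature vector evaluated with pooled-covariance LDA under
   stratified 10-fold cross-validation.

## The directed return random walk

Given a weighted adjacency `W` with degree `d(v)` (we use half the total
weighted degree, `d(v) = (in-strength + out-strength)/2`, which coincides
with the classic undirected degree on symmetric matrices), the two-step
transition score from `i` to `j` through transit `k` is

$$p_k(j \mid i) = \frac{W_{ik} W_{kj}}{d(i)\,d(j)}.$$

The RRW score of the ordered pair demands a *different* return transit:

$$We_{ij} = \max_k \max_{l \ne k}\; p_k(j \mid i)\, p_l(i \mid j).$$

Forcing `l != k` is the heart of the filter: inside a coherent cluster many
alternative return routes exist and the score stays high; a noise edge
between clusters typically has only one two-step route, so no valid
`(k, l)` pair exists and the score collapses to zero (we define the empty
maximum as 0, with `NA` transit indices).

Two corrections follow, both evaluated on the maximizing cycle
`i -> k* -> j -> l* -> i`:

* **Path attenuation**: $We'_{ij} = We_{ij}\,e^{-\gamma_{ij}/\mathrm{Path}_{ij}}$,
  where $\mathrm{Path}_{ij}$ sums the four hop weights of the cycle and
  $\gamma_{ij}$ is the shortest-path distance from `i` to `j` with hop cost
  `1/W`. We read the exponent as the *ratio* $\gamma/\mathrm{Path}$: a weak
  cycle (small Path, long shortest path) must be attenuated strongly, which
  only the ratio form delivers; the product form is available through
  `exponent_form = "product"` for comparison, and hop-count distances
  through `distance = "hops"`.
* **Go/return imbalance**: $We''_{ij} = We'_{ij}\, b_{ij}$ with
  $b_{ij} = (W_{ik^*} + W_{k^*j})/(W_{jl^*} + W_{l^*i})$. A low `b` marks an
  edge that is easy to traverse but hard to return from by a different
  route — the signature of an inter-class edge. `b` is applied unclamped,
  so go-dominant edges are amplified; this is exactly the channel through
  which planted in/out imbalance survives the filter.

Because any pair joined by a two-step go-and-return cycle receives a score,
the output is denser than the input — the RRW doubles as a link predictor.
A brute-force oracle (`brute_force_rrw_oracle`, exhaustive enumeration plus
a hand-rolled Floyd–Warshall) validates the fast implementation exactly on
every graph up to 15 nodes; the tie between equal-scoring transit pairs is
broken toward the lexicographically smallest `(k, l)` in both routes.

## The preconditioning stage

`precondition` composes four steps:

1. **Walk sampling** (`sample_walks`): random walks with a *return policy* —
   at each step the walker goes back to its previous position with
   probability `return_prob` (default 0.15), otherwise moves to an
   out-neighbour with probability proportional to the edge weight.
2. **Skip-gram embedding** (`learn_embedding`): node vectors are trained by
   single-threaded SGD with negative sampling over co-occurrence pairs
   within a window along each walk. All randomness flows through R's RNG,
   so a fixed seed gives bitwise-reproducible embeddings. Defaults:
   dimension 64, 10 walks per node of length 40, window 5, 5 negatives,
   5 epochs, initial learning rate 0.025 with linear decay. None of these
   is critical; they are ordinary values for walk-based embeddings of
   ~100-node graphs and all are exposed in `embedding_config()`.
3. **Embedding kNN rebuild** (`rebuild_knn`): each node connects to its
   `knn_k` nearest embedding neighbours with the Gaussian affinity
   $\exp(-\lVert x_i - x_j\rVert^2/\sigma)$ (the concrete choice of
   sub-Gaussian kernel); $\sigma$ self-tunes to the median squared pairwise
   distance.
4. **Katz-modulated Laplacian regularization** (`katz_centrality`,
   `laplacian_regularize`): the ranking matrix solves
   $(\alpha\Lambda + L)A = \alpha\Lambda$ with `L` the Laplacian of the
   symmetrized rebuilt graph and $\Lambda_{ii} = \lambda_i / C(i)$, where
   `C` is Katz centrality and $\lambda_i$ is 1 (`lambda_mode = "identity"`,
   for dense graphs) or the degree (`"degree"`, for locally sparse ones).
   Dividing by centrality makes high-centrality nodes absorb less, so the
   global structure modulates the local diffusion. `A` is the minimizer of
   $\alpha\,\mathrm{tr}\!\left[(A - I)^\top \Lambda (A - I)\right] +
   \gamma\,\mathrm{tr}(A^\top L A)$ at $\gamma = 1$; it tends to the
   identity as $\alpha \to \infty$, which the tests exercise as an analytic
   limit. The final graph connects each node to the `knn_k` peers whose
   absorption profiles (rows of `A`) are closest, weighted by the same
   Gaussian kernel, and candidates are restricted to the rebuilt graph's
   directed support so directionality survives the symmetric
   regularization step.

Design notes on genuinely open points:

* The Laplacian step presumes a symmetric weight matrix; we symmetrize with
  `max(W, t(W))` for that step only and restore direction by support
  masking.
* Centrality could enter the affinity in several ways; we scale
  $\Lambda_{ii} \leftarrow \lambda_i / C(i)$, the smallest change that
  makes the penalty per unit absorption grow for low-centrality nodes.
* The printed form of the ranking objective is scale-ambiguous; we use the
  form whose exact minimizer is $(\alpha\Lambda + L)^{-1}\alpha\Lambda$,
  and the test suite verifies the solver against direct gradient-descent
  minimization of that objective.

## Degree asymmetry and group comparison

On the binarized graph, `d_in` and `d_out` are column and row sums; their
global totals are always equal, so asymmetry can only concentrate in
specific nodes, never inflate globally (a conservation law the tests
enforce). Per subject, nodes are sorted by `d_in - d_out` ascending and
ranked `96` down to `1` (ties by node index). For each of the 48
left/right ROI pairs we aggregate the subject-mean left and right values —
ranks by default, raw differences via `use_ranks = FALSE` — and their
difference; regions are ordered by the absolute between-group difference
of these left–right gaps. Group differences per region are tested with the
two-sided Mann–Whitney U test (normal approximation with continuity
correction); raw p-values are reported, with a Benjamini–Hochberg column
added as a clearly-labeled extension. The difference form of the
in/out-degree statistic is the default because the ratio is undefined for
nodes without outgoing edges; an add-one-smoothed ratio is available.

## Classification

Features are the raw `(d_in, d_out)` of the left and right node of each of
the six most asymmetric regions (24 features). The classifier is a
pooled-covariance Fisher discriminant written in the package: with 24
integer-valued features and folds of a few subjects, the pooled covariance
is frequently singular, so the solver escalates a small ridge on the
diagonal until the system is well conditioned — deterministic and robust
where off-the-shelf LDA implementations reject constant within-group
columns. (`MASS::lda` serves as an independent cross-check on
well-conditioned data in the test suite.) Folds are stratified by class —
the protocol only says "randomly divide", but unstratified folds of
40-per-class cohorts can lose a class entirely — and the fold assignment is
shared between the filtered and unfiltered arms of `compare_pipelines` so
the comparison is paired. The across-fold standard deviation of accuracy
is reported alongside the mean; sensitivity, specificity and precision
come from the pooled confusion matrix with the affected group as the
positive class.

## What the synthetic cohorts emulate

`generate_cohort` draws, per subject, a random directed graph over 96
nodes with edge density uniform in (0, 1) and uniform (0, 1] weights —
the mixed-severity population used for the asymmetry-expansion and
threshold-sweep experiments. The uniform weight law is our choice; the
reference protocol only requires weights between 0 and 1.

`generate_two_class_cohort` adds labels: healthy subjects are denser random
graphs; affected subjects are sparser, and the right-hemisphere node of
each designated pair has incoming weights scaled by `1 + s` and outgoing
weights by `1 - s`. Scaling weights rather than deleting edges perturbs
both the degree and the weight channel, mirroring go/return links with
asymmetric weights. Defaults, chosen once: 40 subjects per class;
densities 0.15 (healthy) and 0.10 (affected), matching the sparsity of the
k = 15 out-kNN graphs the pipeline actually operates on (15/95 of ordered
pairs) with the affected class thinned to model progressive disconnection;
`s = 0.6` for region-recovery experiments and `s = 0.3` as the "moderate"
setting for the paired classification comparison (at `s = 0.6` both arms
saturate at 100% and the comparison is uninformative). The planted pairs
default to the two parahippocampal regions (nodes 34/82 and 35/83).
The choice of ER-style graphs matters: on *dense* ER graphs (density 0.3+)
the RRW has no cluster structure to exploit and filtering can cost
accuracy; the filter earns its keep precisely in the sparse, kNN-scale
regime it was designed for.

`generate_bold_timeseries` produces white-noise series in which designated
pairs are lag-shifted copies plus Gaussian noise. The default length of
130 samples mirrors a 140-volume acquisition with the first 10 volumes
discarded. These series have no hemodynamic smoothing, no autocorrelation
and no spatial structure, so passing tests demonstrate correct recovery of
planted lag structure — not realism of BOLD dynamics.

## Numerical conventions

* Thresholding keeps exactly `ceiling(c * nnz)` edges; ties at the cutoff
  break by (source, target) lexicographic order.
* The RRW maximization breaks ties toward the smallest `(k, l)`; scores of
  exactly zero yield `NA` transit indices.
* Degenerate (constant) series give correlation 0 with a warning flag.
* The Katz attenuation self-tunes to `0.85 / rho(W)` when unset and the
  solver refuses attenuations at or beyond `1/rho` with the computed
  spectral radius in the message.
* Walks from isolated nodes have length 1; nodes absent from every walk
  receive a zero embedding vector with a warning.
* A single global pipeline seed fans out to per-stage seeds through a fixed
  hash of the stage name (`stage_seed`), so each stage is independently
  reproducible.

## Problem sizes used in the shipped checks

The package's property checks run the full pipeline at the reference scale
of 500 subjects by 96 regions for the expansion and threshold-sweep
experiments, 20 seeded cohorts (40 subjects per class) for region-pair
recovery, and 25 seeded replicates for the paired classification
comparison. The preconditioning checks (densification, local isotropy)
use 15–30 sparse graphs; these are averages over independently generated
graphs, and the chosen counts give stable means. On our reference
synthetic cohort the asymmetry-maximizing threshold comes out at c = 50%,
adjacent to the 40% working default; the sweep exists precisely because
this maximizer is cohort-dependent.

## Known limitations

* The RRW enumeration is O(n^2) pairs with O(n) work per pair plus an
  all-pairs shortest-path pass; comfortable at n = 96, not intended for
  thousands of nodes.
* The two-class generator plants asymmetry multiplicatively at designated
  right-hemisphere nodes; it does not model correlated asymmetries across
  regions, scanner artifacts, or inter-subject atlas misalignment.
* Synthetic ER cohorts have no community structure beyond what is planted,
  so the absolute accuracies reported by the classification experiments
  say nothing about accuracy on real fMRI cohorts — only the *ordering*
  of the filtered vs unfiltered arms is meaningful.
* One preconditioning cycle is the default; extra re-ranking cycles are
  supported (`rerank_cycles`) but not exercised by the shipped experiments.
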