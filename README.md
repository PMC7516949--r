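# rrwasym

Detection of left–right hemispheric asymmetries in directed brain
activation networks, using a directed **Return Random Walk** (RRW) link
predictor as a structural noise filter.

## What problem this solves, and for whom

Functional MRI connectivity is usually analyzed as an undirected
correlation graph, which cannot express *which* region leads an
interaction. Representing each subject as a directed weighted graph over
96 regions of interest (48 per hemisphere) lets us measure, per region,
the imbalance between incoming and outgoing links — and compare that
imbalance between the left and right member of each anatomical pair.
Early neurodegeneration is hypothesized to break this left–right balance
in specific regions before global statistics move, but the signal is
buried in structural noise: spurious inter-cluster edges from noisy lagged
correlations.

This package is for researchers who want to run or study that analysis
end-to-end on directed graphs: it implements the graph construction, the
noise-filtering mathematics, the asymmetry statistics, the group
classification, and — because clinical imaging data is access-restricted —
a synthetic-cohort generator that makes every stage testable and
reproducible at the published scale (500 subjects × 96 regions).

## The core statistic

For a weighted digraph `W` with degree `d(v)` (half the total weighted
degree), the directed RRW rescores every ordered pair by its best two-step
go-and-return cycle through *distinct* transit nodes:

    We_ij  = max_k max_{l≠k}  [ W_ik W_kj / (d_i d_j) ] · [ W_jl W_li / (d_j d_i) ]
    We'_ij = We_ij · exp( −γ_ij / Path_ij )          γ: shortest path (cost 1/W)
    We''_ij = We'_ij · (W_ik* + W_k*j) / (W_jl* + W_l*i)

Inside a coherent cluster many return routes exist and the score stays
high; a noise edge between clusters has no alternative return and the
score collapses. The final factor `b` amplifies go-dominant edges, which
is how planted in/out imbalance survives — and is expanded by — the
filter. Downstream, each node's asymmetry is `d_in − d_out` on the
binarized graph (top 40% of weights), aggregated over the 48 left/right
region pairs, compared between groups by Mann–Whitney U tests, and fed as
24 degree features (six most asymmetric regions × 4 degrees) into a
pooled-covariance LDA under stratified 10-fold cross-validation.

## Worked example

```r
library(rrwasym)

# a labeled synthetic cohort: 40 healthy + 40 affected subjects, with
# moderate asymmetry planted in the two parahippocampal region pairs
ch <- generate_two_class_cohort(n_per_class = 40, asymmetry_strength = 0.3,
                                seed = 42)
ch[[1]]$graph
#> weighted digraph: 96 nodes, 1448 edges (density 0.159)
#>   weights in [7.589e-05, 0.9996]

apply_directed_rrw(ch[[1]]$graph)
#> directed RRW result: 96 nodes
#>   nonzero scores: We 7548, We' 7548, We'' 7548 (of 9120 ordered pairs)

cmp <- compare_pipelines(ch, seed = 42)
cmp
#> pipeline comparison (identical folds)
#>   with RRW:    100.00% accuracy
#>   non-filtered: 100.00% accuracy
#>   difference:  +0.00 points

cmp$regions_with_rrw
#> [1] "Parahippocampal Gyrus, posterior division"
#> [2] "Region 20"
#> [3] "Region 47"
#> [4] "Region 30"
#> [5] "Parahippocampal Gyrus, anterior division"
#> [6] "Region 25"
```

Reading the output: the RRW filter densifies the sparse input (7548 scored
pairs from 1448 edges) by predicting links along go-and-return cycles.
Both planted parahippocampal pairs surface among the six most asymmetric
regions. On this seed both classification arms reach 100%; across 25
seeded replicates the filtered arm matches or beats the unfiltered arm
(about 100% vs 98% mean accuracy — the paired comparison shares fold
assignments, so the difference is attributable to the filter alone).

A thin command-line wrapper over the same functions is provided at
`inst/cli/rrwasym.R` (subcommands `synth`, `rrw`, `sweep`, `pipeline`).

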