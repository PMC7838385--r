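# fmenr

Functional molecular ecological networks (fMENs) from functional gene
array data.

Functional gene microarrays (GeoChip-style) measure the abundance of
thousands of biogeochemical marker genes — carbon, nitrogen, phosphorus and
sulfur cycling, stress response — across environmental samples. fmenr is
for microbial ecologists who want to go from raw probe signals to a
quantitative comparison of two sample groups (the motivating design is
lakes at ~530 m versus ~4,600 m elevation, 12 water samples per group) and
to an inferred gene co-occurrence network whose threshold is chosen by an
objective random-matrix-theory criterion rather than by hand.

The pipeline:

1. **Preprocessing** — keep probe cells with signal-to-noise ratio > 2,
   keep probes detected in ≥ 2 of 6 samples of some lake, `ln(x+1)`
   transform, divide by each sample's positive-control mean, and
   (optionally) convert to relative intensities. The group contrast per
   gene family is `(S_high / S_low) − 1`.
2. **Group statistics** — richness, shared/unique gene overlap, and Welch
   t tests on summed intensities per category, subcategory, gene family or
   (lineage × category) aggregate.
3. **Dissimilarity tests** — PERMANOVA (pseudo-F from distance sums of
   squares), ANOSIM (rank-based R) and MRPP (weighted within-group
   distance δ) on Euclidean / Bray–Curtis / Morisita–Horn matrices, with
   seeded free label permutations, the add-observed convention
   `p = (1 + hits)/(n_perm + 1)`, and exact exhaustive enumeration on
   small designs.
4. **RMT network inference** — Pearson correlations across a group's
   samples; the similarity threshold `st` is the smallest one at which the
   nearest-neighbour spacing distribution of the unfolded eigenvalues of
   the thresholded matrix turns (and stays) Poisson, `P(s) = e^(−s)` — the
   signature of a system decomposed into nearly independent modules —
   rather than Wigner–Dyson, `P(s) = (πs/2)e^(−πs²/4)`.
5. **Topology and null models** — `avgK = 2L/n`, harmonic geodesic
   distance, clustering, transitivity, fast-greedy modularity, power-law
   R², and Z tests against 100 degree-preserving (or size-matched) random
   networks.
6. **Node roles and environment** — within-module degree z-score `Zi` and
   participation coefficient `Pi = 1 − Σ(k_is/k_i)²` with the standard
   role thresholds (network hubs: Zi > 2.5 and Pi > 0.62; module hubs:
   Zi > 2.5; connectors: Pi > 0.62); module eigengenes (first principal
   components) correlated with environmental variables by Spearman rank.

A seeded synthetic-data generator (`generate_dataset()`) emulates the
study design — 4 lakes × 6 samples, planted stress-response fold-changes,
planted correlation modules, planted environmental driver — with a ground
truth ledger, so every stage is exercised and calibrated without the
original microarray data.

## Worked example

```r
library(fmenr)
library(dplyr)

d <- generate_dataset(synth_config(seed = 42))
sig <- d$signal |>
  filter_by_snr() |>
  filter_by_prevalence(d$design) |>
  normalize_signals()

category_ttest(sig, d$design, d$annotation) |> arrange(p_value)
#> # A tibble: 6 × 5
#>   unit             mean_low mean_high statistic p_value
#>   <chr>               <dbl>     <dbl>     <dbl>   <dbl>
#> 1 stress response      62.2      66.1     2.95  0.00747
#> 2 nitrogen cycling     50.1      51.6     1.21  0.240
#> 3 other                24.1      25.0     0.997 0.330
```

The planted 1.5× stress-response effect is the only category flagged
(p = 0.007): its summed normalized intensity is higher in the high-elevation
group, and no unplanted category reaches p < 0.05.

Network inference on a full-detection dataset (dropout-free, so the planted
correlation blocks are the ground truth):

```r
dc <- generate_dataset(synth_config(detection_prob = 1, snr_fail_prob = 0,
                                    seed = 42))
sigc <- dc$signal |> filter_by_snr() |>
  filter_by_prevalence(dc$design) |> normalize_signals()
genes <- select_common_genes(sigc, dc$design, dc$annotation, "low")
corr  <- pearson_matrix(sigc, genes = genes,
                        samples = dc$design$sample_id[
                          dc$design$elevation_group == "low"])

scan <- select_threshold(corr)
glance(scan)
#> # A tibble: 1 × 3
#>   selected_st n_thresholds n_poisson
#> 1        0.76           70        17

net <- build_network(corr, attr(scan, "selected_st"),
                     annotation = dc$annotation)
net
#> fMEN: 264 nodes, 628 links at st = 0.76 (97.1% positive)

topology_summary(net, fast_greedy_modules(net))
#> # A tibble: 1 × 9
#>       n links avg_k    hd avg_cc transitivity modularity n_modules powerlaw_r2
#> 1   264   628  4.76  10.2  0.398        0.733      0.845        31       0.514
```

The scan finds the Wigner-to-Poisson transition at st = 0.76; the resulting
network is strongly modular (Q = 0.85) and far more clustered than its
degree-preserving nulls (`random_ensemble(net)`). `node_roles()`,
`module_eigengene()` and `env_correlation()` then classify hub/connector
genes and tie module eigengenes to environmental variables —
`autoplot()`, `plot_zipi()`, `plot_degree_distribution()` and
`plot_module_env()` draw the standard displays, and `run_pipeline()` chains
all stages into one reproducible, seeded report.

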