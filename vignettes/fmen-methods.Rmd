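---
title: "Methods: from probe signals to functional molecular ecological networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from probe signals to functional molecular ecological networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

fmenr analyses functional gene microarray (GeoChip-style) surveys of
microbial communities sampled under contrasting conditions — the motivating
design is lakes at low (~530 m) versus high (~4,600 m) elevation, four lakes
with six water samples each, giving 12 biological replicates per elevation
group. This vignette is the package's own account of the models and
procedures it implements, the tunable parameters and the reasoning behind
the design choices that were genuinely open.

## Signal preprocessing

A probe cell (one probe in one sample) enters the analysis only if its
signal-to-noise ratio is strictly greater than 2 (`filter_by_snr()`), and a
probe is retained only if it is detected in at least 2 of the 6 samples of
some lake (`filter_by_prevalence()`; with unequal lake sizes the rule
generalizes to `ceiling(0.3 * n)`). Retained signals are `ln(x + 1)`
transformed and divided, per sample, by the mean intensity of that sample's
positive-control probes (`normalize_signals()`), which removes
between-array brightness differences. Relative intensities
(`relative_intensity()`) divide each normalized value by its sample total,
so every sample column sums to 1.

Two choices here were open and are worth stating:

* **Order of transform and control-scaling.** Whether the positive-control
  division applies to raw or to log-transformed intensities is ambiguous in
  the GeoChip literature's shorthand. The default transforms first and
  divides by the mean of the *transformed* controls, keeping both operands
  on the same scale; `divide = "raw"` gives the alternative. The two differ
  only by a smooth monotone reparameterization and do not change detection
  calls or rank-based statistics.
* **Undetected cells are zeros, not missing.** Richness and relative
  intensities need a complete matrix. The correlation stage re-protects
  itself by its own prevalence rule (below), but zeros do enter correlations
  for genes detected in only part of a group — see the caveat under
  *What the generator does and does not emulate*.

The group contrast for a gene family (or subcategory, or category) is
`delta = S_high / S_low - 1`, with `S` the total intensity over member
probes and group samples; `delta = 0.5` reads as "50% higher at high
elevation". Units with `S_low = 0` are flagged rather than divided.

## Group statistics

Richness counts probes with positive normalized intensity; overlap
statistics compare each group's detected set with percentages on the union
(per-group denominators are emitted alongside, since published figures use
both conventions). Per-unit group tests sum member-probe intensities within
each sample and compare groups with a two-sample t test — Welch by default,
because nothing guarantees equal variances between groups with such
different environments; the pooled variant is available. Raw p-values are
reported, with an optional Benjamini–Hochberg column; the default mirrors
the unadjusted p < 0.05 convention of the source field.

## Permutation tests on dissimilarity matrices

`distance_matrix()` supports Euclidean, Bray–Curtis and Morisita–Horn
dissimilarities (via vegan). Three permutation tests are implemented
in-package so that their permutation schemes are fully controlled:

* **PERMANOVA**: pseudo-F from distance-based sums of squares,
  `F = ((SS_T - SS_W)/(a-1)) / (SS_W/(N-a))`.
* **ANOSIM**: `R = (mean between-group rank − mean within-group rank) /
  (n(n−1)/4)` with mid-ranks for ties.
* **MRPP**: `delta = sum_g (n_g/N) ×` mean within-group distance; small
  delta means tight groups, so the permutation tail is the lower one.

All three permute whole-sample labels freely and use the add-observed
convention `p = (1 + hits)/(n_perm + 1)`, so p = 0.001 is attainable with
999 permutations. With `exact = TRUE` every distinct labeling is enumerated
and the p-value is exact — used by the test suite on 4–10-sample designs
where the full enumeration is small. Free permutation treats the 12 samples
per group as exchangeable, which mirrors the source design's pooled
contrast; samples within a lake are pseudo-replicates under that scheme.
The `strata` argument instead swaps group labels between whole lakes, the
conservative alternative; it is off by default to match the pooled
convention, and with only two lakes per group its permutation null is very
coarse (six distinct labelings).

The test suite calibrates the size of all three tests by simulation: 1,000
null datasets on a 5 + 5 design with exhaustively enumerated p-values give
empirical type-I error within 0.03–0.07 at α = 0.05. A 4 + 4 design is too
discrete for that check: with equal groups the label-swap symmetry doubles
every count, so the attainable size just below 0.05 is 2/70 ≈ 0.029.

## RMT network inference

The functional molecular ecological network (fMEN) is built from the
Pearson correlation matrix of gene profiles across one group's samples,
restricted to genes in the key process categories (carbon, nitrogen and
phosphorus cycling, stress response) detected in at least half of the
group's samples. The similarity threshold `st` is not hand-picked: it is
selected by the random-matrix-theory criterion on the eigenvalue spectrum
of the thresholded similarity matrix (entries `|r| >= st`, diagonal 1,
genes with no surviving off-diagonal entry removed).

The diagnostic is the nearest-neighbour spacing distribution (NNSD) of the
*unfolded* eigenvalues. A dense correlated system has Wigner–Dyson (GOE)
spacings, `P(s) = (pi s/2) exp(-pi s^2/4)`; a system decomposed into many
nearly independent blocks has Poisson spacings, `P(s) = exp(-s)`, because
superposing many independent spectra destroys level repulsion. The scan
walks an ascending grid of thresholds (default 0.30–0.99, step 0.01) and
selects the smallest one whose spacing verdict is Poisson and stays Poisson
over the next few grid points.

Numerical choices, fixed once:

* **Unfolding** maps eigenvalues through a cubic smoothing spline fitted to
  the cumulative spectral function (staircase), `df = 20`, after collapsing
  degenerate eigenvalues (tolerance 1e-8). A literal empirical-CDF mapping
  is unusable — it sends every spacing to exactly 1 — and very flexible
  fits begin to absorb the level repulsion that distinguishes GOE from
  Poisson. df = 20 tracks the sharp eigenvalue bulk produced by
  near-rank-one modules while keeping the GOE/Poisson discrimination exact
  on reference spectra (20/20 seeds each in the test suite). Mean unfolded
  spacing is 1 within 5%.
* **Goodness of fit** is a one-sample Kolmogorov–Smirnov test against each
  spacing law at α = 0.05; the verdict is Poisson when the Poisson fit is
  not rejected and the Wigner fit is, GOE for the converse, ambiguous
  otherwise. A chi-square variant (bin width 0.5) is available but is
  noticeably less robust on a few hundred spacings.
* **Stability window.** The Poisson verdict must persist for the next 3
  assessable grid values. Demanding Poisson over the *entire* remaining
  grid is not workable: just below the strongest correlations the graph
  fragments, eigenvalues pile up into near-degenerate clusters, and the
  spacing test rejects everything; every realistic scan would fail. Three
  consecutive confirmations skip isolated false Poisson verdicts in the
  transition region while still finding the genuine plateau.
* **Thresholding uses `|r|`**, so negative associations survive as edges
  with a sign attribute; empirical fMENs carry large negative-link
  fractions and discarding them would bias every topology index.
* At least 50 surviving genes are required for a spacing distribution;
  below that the verdict is unassessable, not evidence either way.

`build_network()` materializes the graph at the selected threshold (edge
iff `|r| >= st`, weight `|r|`, sign from `r`, isolated genes dropped), and
`powerlaw_r2()` reports the ordinary least-squares R² of
log10(frequency) on log10(degree) — the conventional scale-free summary,
reported as a descriptive index rather than a hypothesis test.

## Topology, modules and null ensembles

`topology_summary()` works on the unweighted, unsigned, simple graph:
average connectivity `avgK = 2L/n`; harmonic geodesic distance
`HD = [ (2/(n(n-1))) sum 1/d_ij ]^(-1)` with disconnected pairs
contributing zero reciprocal (so sparse graphs get finite values);
average clustering coefficient with degree < 2 nodes contributing 0;
global transitivity; and modularity from fast greedy agglomeration
(`fast_greedy_modules()`, deterministic; the dendrogram is cut at its own
maximum-modularity step). The suite verifies Q = 0.5 on two disjoint
triangles, agreement with an exhaustive search over all 4,140 partitions of
an 8-node toy, and the definitional recomputation of Q from the returned
partition.

`random_ensemble()` draws 100 random networks per comparison. The default
null preserves every node's degree by repeated double-edge swaps (10 × L
rewiring trials, no self-loops or multi-edges) — the stricter and more
informative null; `size_links` (same n and L, otherwise uniform) is
provided because "same size and average number of links" is also a
defensible reading. Differences are summarized by `Z = (empirical − null
mean)/null sd` with a two-sided normal p.

## Node roles and module–environment analysis

Within-module connectivity `Zi` is the z-score of a node's within-module
degree among its module's members (Guimerà–Amaral construction; modules of
size 1 or zero spread give Zi = 0, flagged); among-module connectivity
`Pi = 1 − sum_s (k_is/k_i)^2`. Roles use the standard thresholds — network
hubs (Zi > 2.5 and Pi > 0.62), module hubs (Zi > 2.5), connectors
(Pi > 0.62), peripherals otherwise. The inequalities are strict, so exact
boundary values classify downward; this is stated because the thresholds
are conventional, not estimated.

The module eigengene `E` is the first principal component of the module's
standardized member profiles across samples, sign-oriented so that its mean
correlation with member profiles is positive; "top modules" means the five
largest by node count. Eigengenes are computed from normalized (not
relative) intensities by default — relative intensities couple genes
through the per-sample total, which would leak compositional structure into
every module. Module–environment association uses mid-rank Spearman
correlation with two-sided p-values.

## The synthetic data generator

`generate_dataset()` emulates the study conditions: 4 lakes × 6 samples,
two elevation groups, 400 probes plus ~2% positive-control probes with a
common mean. Intensities are lognormal (positive, right-skewed,
multiplicative noise; log-scale sd 0.35 around probe-specific means near
ln 2000). Planted structure, recorded in a truth ledger:

* **Group effect**: stress-response probes (20% of probes) have their mean
  multiplied by `stress_effect` (default 1.5, matching the ~50% increases
  reported for key stress genes) in high-group samples.
* **Correlation modules**: 10 blocks of 12 probes share per-sample latent
  factors; a member's log deviation is `sqrt(w)·factor + sqrt(1−w)·noise`
  with `w = within_module_r = 0.9`, so within-block correlation is `w`.
  Ten blocks, not fewer: the RMT criterion presumes the thresholded system
  decomposes into *many* independent blocks (Poisson spacings arise from
  superposing many spectra); a 3-module system never shows a Poisson
  plateau and would violate the method's own working assumption, whereas
  empirical fMENs carry dozens to hundreds of modules.
* **Detection**: each cell is detected with probability 0.9, independently
  of intensity, and 10% of detected cells draw SNR ≤ 2, so both filters
  have non-trivial work.
* **Environment**: covariates differ between groups in fixed directions
  (low-elevation lakes warmer, richer in DOC, chlorophyll a and nutrients);
  turbidity is additionally driven by module 1's latent factor
  (coupling 1.5). Turbidity is the driver because it carries no group
  offset — a group-contrasted variable would rank-order by group and mask
  the factor coupling that the eigengene analysis is meant to recover.

**What the generator does and does not emulate.** It reproduces the
two-group design, positive skewed signals, planted group effects,
modular correlation structure, detection dropout and SNR failures. It does
not emulate probe cross-hybridization, scanner artifacts, taxonomic
structure in the correlations, or — importantly — compositional differences
in *which* genes occur in each group. Two consequences for interpreting the
tests: dissimilarity-based separation driven purely by a 1.5–2× intensity
effect on one category is weak once 10% random dropout dominates
between-sample distances, so the concordance property for the three
permutation tests is checked under full detection; and random co-absence of
probe pairs creates spurious strong correlations in 12-sample groups, so
the network parameter-recovery quantities are also computed under full
detection, where the planted correlation structure is the ground truth
being recovered. Passing these tests therefore demonstrates that the
machinery recovers known structure under its working assumptions — not that
real dropout-ridden data are free of co-absence artifacts. With real data,
the in-network prevalence rule (≥ 50% of group samples) is the guard rail,
and stricter prevalence is the first knob to turn.

## Problem sizes and determinism

Every stochastic step takes an explicit seed, and fixed seeds reproduce
byte-identical tables, networks and reports. The test-suite problem sizes —
120–240-gene spectra for the NNSD checks, 20 generator seeds for the
calibration properties, 1,000 simulations for test size, 400-probe
pipelines — were chosen as the smallest sizes at which the checked
properties are stable, and run in about two minutes total.

## Known limitations

* Pearson correlation across 12 samples is noisy; the RMT scan compensates
  by thresholding hard, but networks from small groups should be read
  qualitatively.
* The NNSD verdict at any single threshold is a hypothesis test at
  α = 0.05 and inherits its error rates; the stability window, not any one
  verdict, carries the selection.
* Fast greedy modularity has the usual resolution limit; very small modules
  may be absorbed into neighbours.
* The analytic machinery reproduces published network indices only given
  the same input data; with synthetic inputs the package checks identities
  (e.g. `avgK = 2L/n` on the published n and L) and recovery properties,
  not the published table values themselves.
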