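---
title: "Inferring community assembly processes and co-occurrence structure from OTU tables"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring community assembly processes and co-occurrence structure from OTU tables}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ecoassembly)
```

`ecoassembly` asks, for a set of microbial communities profiled as a
rarefied OTU table: how much of the variation among communities is due to
deterministic niche-based processes (environmental selection) versus
stochastic ones (dispersal, ecological drift), and how are taxa organized
into co-occurrence networks? This vignette explains the models, the
choices behind their implementation, and what the synthetic-data
generator does and does not establish about real data.

## Input data and rarefaction

Every analysis starts from an integer count matrix (samples × OTUs)
rarefied to a common depth. Rarefaction (`rarefy_table()`) draws each
sample's reads without replacement — a multivariate hypergeometric
subsample — so that occupancy and dissimilarity statistics are not
confounded by sequencing effort. A single fixed-seed draw is used rather
than an average over draws: all downstream statistics are either
insensitive to the draw (row sums, occupancy of non-marginal taxa) or
are themselves averaged over many randomizations. All-zero OTU columns
are dropped by default since they cannot contribute to any statistic.

## The Sloan neutral community model

The neutral model treats every individual as ecologically equivalent:
local communities of `N` individuals lose one individual at a time, and
the replacement is an immigrant from the regional pool with probability
`m` (the migration rate) or a local birth otherwise. At stationarity the
local relative abundance of a taxon with regional abundance `p` follows
`Beta(N m p, N m (1 - p))`, so its expected occupancy across communities
is

    freq(p) = 1 - I_d(N m p, N m (1 - p)),   d = 1/N,

where `I_d` is the regularized incomplete beta function and `d` the
detection limit. `fit_ncm()` estimates `m` by bounded least squares of
observed occupancy on this curve. Because the objective has a single
parameter on a bounded interval, a golden-section search over the full
box (`stats::optimize` on (1e-6, 1]) is used instead of multistart
nonlinear least squares; the 1-D profile is smooth and unimodal in
practice, and the search cannot be trapped the way a poorly started NLS
can. `N` is the rarefaction depth (rows are exactly equal), `d = 1/N`,
and OTUs with mean relative abundance below `d` are excluded — the
prediction is degenerate below detection. The 95% interval on `m` comes
from bootstrap resampling of OTUs (1000 replicates by default), and the
per-OTU partition (above / neutral / below the prediction) uses the
Wilson score interval for a proportion observed over `n_samples`
samples.

### What parameter the estimator actually measures

Two approximations relate the fitted `m` to the mechanistic immigration
probability of a finite Moran community, and both matter at moderate
`m`. First, detailed balance for the Moran chain with per-event
immigration probability `m_e` gives an exactly beta-binomial stationary
distribution with scale `m_e (N - 1) / (1 - m_e)` — equal to `N m_e`
only when `m_e` is small. The simulator therefore accepts `m` on the
model's own ("sloan") scale and converts internally
(`m_e = N m / (N - 1 + N m)`), with the raw per-event scale available
via `m_scale = "event"`. Second, the estimator approximates detection
(`count >= 1`) by the beta tail above `1/N`, while the exact detection
probability integrates binomial sampling of the beta; near the detection
limit the discrete community is detected more often than the beta tail
suggests. The recovery tests show the consequence: estimates track the
true ordering tightly and sit modestly above the truth at moderate
migration rates. This is a property of the published estimator, shared
by any implementation of it, and is why fitted `m` values should be read
comparatively (between domains, between zones) rather than as absolute
immigration probabilities.

## Null-model partition of assembly processes

The five-process framework classifies every pair of communities by two
standardized null models.

**Phylogenetic turnover.** `beta_mntd()` computes the abundance-weighted
mean distance from each taxon to its phylogenetically nearest taxon in
the other community. `beta_nti()` standardizes it against a taxa-shuffle
null: each of 999 randomizations (default; tests use 199) permutes all
tip identities across the phylogeny once and the same permutation is
applied to every pair, preserving community composition and tree shape
while destroying the taxon–phylogeny association. `betaNTI` is the
z-score of the observed value. Selection on a phylogenetically conserved
trait leaves |betaNTI| > 2: above +2 when different communities are
filtered toward different optima (variable selection), below −2 when a
shared filter holds communities in the same clades (homogeneous
selection). Pairs with zero null variance (e.g. identical samples) are
reported as missing and excluded.

**Taxonomic turnover.** `raup_crick_bray()` compares observed
Bray–Curtis dissimilarity to nulls in which both communities are
reassembled at random: membership drawn without replacement with
probability proportional to occupancy, then filled to the observed depth
proportionally to regional relative abundance, preserving each sample's
richness and depth. The null quantile rescaled to [−1, 1] flags pairs
more dissimilar than chance (RC > 0.95, dispersal limitation when
selection is absent) or less (RC < −0.95, homogenizing dispersal).

`partition_processes()` applies the standard decision rules
(betaNTI > 2 → variable selection; < −2 → homogeneous selection;
otherwise RC decides among dispersal limitation, homogenizing dispersal,
and the undominated remainder, which is commonly read as drift plus weak
processes — "drift" and "undominated" label the same class). Ties at
exactly |betaNTI| = 2 and |RC| = 0.95 go to the stochastic and
undominated side respectively, the conservative reading of strict
inequalities in the decision rules. Determinism is the sum of the two
selection fractions; stochasticity the remaining three.

## Levins' niche breadth

For OTU *j*, `B_j = 1 / sum_i P_ij^2` where `P_ij` is the share of the
OTU's total count found in sample *i* (so `sum_i P_ij = 1`). This is the
inverse Simpson concentration of the OTU across communities: 1 for a
single-community specialist, `N` (the number of communities) for a
perfectly even generalist. The OTU-margin normalization is the only one
that gives these bounds, which is why it is used even though "proportion
of OTU j in community i" could be read on either margin. `Bcom` is the
mean `B` over taxa present in a sample, computed per sample (group
summaries are distributions of per-sample values, suitable for Tukey HSD
comparisons) rather than pooled per group.

## Co-occurrence networks

`filter_for_network()` keeps OTUs occurring in at least half the
analysis samples, then the 300 most abundant (both defaults
configurable; occupancy is always computed within the analysis set, so
per-zone networks filter within the zone's samples). `build_network()`
computes Spearman correlations with midrank ties over all retained
pairs, two-sided p-values by the t approximation (the same large-sample
route `cor.test` takes in the presence of ties), Benjamini–Hochberg FDR
over the full upper triangle of each network separately, and keeps edges
with |rho| > 0.6 and q < 0.01. The graph is simple, undirected,
unweighted and unsigned for all topology metrics; the correlation sign
is retained as edge metadata only.

Topology metrics follow the standard definitions: average local
clustering with degree-<2 nodes counting zero; path length and diameter
over connected pairs only (the conventional treatment of disconnected
graphs); density `2E/(N(N-1))`; a power-law fit reported as the R² of an
ordinary least-squares line through the non-empty bins of the log–log
degree histogram. Modules come from Louvain modularity maximization run
ten times from different seeds keeping the best partition (the heuristic
is stochastic); Q > 0.4 is the conventional bar for calling a network
modular. `zipi_classify()` computes the within-module degree z-score
(Zi) and among-module participation coefficient (Pi) and applies the
2.5 / 0.62 thresholds: network hubs, module hubs and connectors are
flagged keystone taxa. Modules whose members all have identical
within-module degree have no z-scale; their members get Zi = 0, logged.

Random baselines (`random_ensemble()`) are uniform G(n, m) graphs with
the empirical node and edge counts — 1000 replicates by default — and
summarize clustering, path length and modularity. Robustness
(`robustness_curve()`) tracks natural connectivity, the log-mean of the
exponentiated adjacency eigenvalues, computed stably by shifting by the
leading eigenvalue, as a growing fraction of nodes is removed (random
removal over 100 replicates, or a single targeted descending-degree
curve).

## The synthetic-community generator

Real mangrove-sediment data cannot ship with the package, so every
inference stage is validated against simulations with known ground
truth, mirroring the targeted sampling design: 48 samples in 4 regions ×
4 vegetation zones, log-normal regional abundance distribution
(`simulate_metacommunity`), a Yule phylogeny with a Brownian-motion
trait (`simulate_tree_with_traits`) so that selection acts on a
phylogenetically conserved trait.

- **Neutral regime** (`simulate_neutral_local`): independent Moran
  communities as described above. The default event count scales as
  `1/m_e` because the stationary variance is approached at rate
  `2 m_e / N` per event; a fixed small event count would leave low-`m`
  communities under-dispersed and bias fitted migration rates upward.
- **Selection regimes** (`simulate_niche_local`): multinomial sampling
  with weights `meta_i · exp(-(trait_i - env_s)^2 / (2 sigma_sel^2))`.
  Two environment blocks at ±3 trait SD give variable selection; a
  single shared optimum gives homogeneous selection. Detecting
  homogeneous selection additionally requires membership turnover among
  samples — identical communities carry no signal because shared taxa
  contribute zero to phylogenetic turnover under every tip shuffle — so
  the homogeneous-selection test scenario uses a large pool, shallow
  samples and a tight filter at an extreme trait optimum, which lets
  drift vary membership while selection holds the clade.
- **Dispersal limitation** (`simulate_dispersal_limited`): each region
  receives a Dirichlet-resampled copy of the metacommunity
  (concentration `alpha0 · meta`, default `alpha0 = 10`) and samples are
  multinomial draws from their regional pool. The default makes regional
  pools overlap weakly, so between-region pairs exceed the RC_Bray 0.95
  bound without generating a phylogenetic selection signal, while
  within-region pairs are more similar than chance (homogenizing
  dispersal) — both signatures of restricted dispersal.

All simulators are bit-reproducible under a fixed seed and produce rows
summing exactly to `n_individuals`.

**What passing tests show — and do not.** The simulations demonstrate
that each estimator recovers the process that generated the data at
desk scale (24–48 samples, 150–500 OTUs, depths 200–1000, 199
randomizations in tests; the package defaults are 999 randomizations and
1000 bootstrap/ensemble replicates). They do not emulate compositional
artifacts of amplicon sequencing (copy-number variation, primer bias,
chimeras), spatially explicit dispersal, or temporal dynamics, and a
single Gaussian trait is a deliberately minimal stand-in for
multidimensional niches. Conclusions about real sediment communities
inherit the assumptions of the published framework, not of the
generator.

## Numerical conventions and degenerate inputs

- Shannon diversity uses natural logarithms (the common ecology
  default); a `base` argument switches scales.
- Abundance-category thresholds: "< 0.1%" is strict, "≥ 1%" inclusive;
  an OTU at exactly 0.1% everywhere is moderate, not rare.
- Preston octaves use doubling classes with boundary counts split
  between adjacent octaves (`vegan::prestonfit`); the quasi-Poisson
  octave regression and the log2 maximum-likelihood variant are both
  exposed, and the extrapolated richness is the Gaussian area
  `S0 · sigma · sqrt(2π)`.
- Spearman edges from constant OTU vectors are undefined; such OTUs are
  dropped with a message. Identical-rank pairs get p = 0 rather than the
  t approximation's NaN.
- Tie-breaks in the abundance filter are by OTU identifier, making
  network construction bit-reproducible.
- The pipeline derives one seed per stage from the master seed, so a
  single integer fixes an entire `run_pipeline()` run.

## Known limitations

- The NCM migration rate carries the estimator-intrinsic upward bias
  discussed above; comparative statements are robust, absolute ones are
  not.
- The taxa-shuffle null is the framework's convention; richness- or
  abundance-constrained phylogenetic nulls would answer slightly
  different questions and are not implemented.
- RC_Bray nulls cost O(pairs × randomizations) community assemblies;
  very large sample sets should reduce `n_null` or parallelize over
  pairs upstream of this package.
- Louvain maximizes modularity greedily; with ten seeded restarts the
  best Q is stable on the graph sizes used here, but module *labels*
  are arbitrary.
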