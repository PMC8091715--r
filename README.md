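# ecoassembly

Community assembly inference and co-occurrence network analysis for
microbiome OTU tables.

Microbial communities — for instance the archaea and bacteria of
estuarine and mangrove sediments — are structured by a mix of
deterministic processes (environmental selection) and stochastic ones
(dispersal and ecological drift). `ecoassembly` implements, as one
tested R pipeline, the statistical toolkit ecologists use to weigh these
processes from a rarefied OTU table, a sample metadata table and a
phylogeny, plus the network analysis used to describe co-occurrence
structure and keystone taxa. It is aimed at microbial ecologists who
want these analyses reproducible and testable end to end rather than
scattered over scripts.

## What it computes

**Sloan neutral community model** (`fit_ncm`). Under neutral birth–death
dynamics with migration rate *m*, a taxon with regional relative
abundance *p* has local abundance distributed Beta(*Nmp*, *Nm*(1−*p*)),
so its expected occupancy is

    freq(p) = 1 − I_{1/N}(Nmp, Nm(1−p))

with *N* the reads per sample and *I* the regularized incomplete beta
function. *m* is fitted by bounded least squares of observed occupancy
against this curve, with R², a bootstrap CI, and a per-OTU
above/neutral/below partition from Wilson score bands.

**Five-process null-model partition** (`beta_nti`, `raup_crick_bray`,
`partition_processes`). Phylogenetic turnover (betaMNTD) is standardized
against 999 taxa-shuffle randomizations into betaNTI; taxonomic
turnover is standardized by a Bray–Curtis Raup–Crick null that
reassembles communities preserving richness and depth. Pairwise
comparisons are classified as variable selection (betaNTI > 2),
homogeneous selection (betaNTI < −2), dispersal limitation
(|betaNTI| < 2, RC > 0.95), homogenizing dispersal (RC < −0.95), or
undominated/drift.

**Levins' niche breadth** (`levins_breadth`, `community_breadth`).
*B_j* = 1/Σᵢ *P²ᵢⱼ* per OTU and its per-sample mean *Bcom*, the
generalist–specialist spectrum at community level.

**Diversity utilities** (`alpha_diversity`, `rarefaction_curve`,
`classify_abundance_categories`, `preston_fit`, `tukey_hsd`). Richness
and Shannon–Wiener, Monte-Carlo rarefaction curves, the six
rare/abundant taxon categories (AAT/ART/MT/CRT/CAT/CRAT at 0.1%/1%),
truncated Preston log-normal sampling-coverage estimates, and Tukey HSD
group comparisons.

**Co-occurrence networks** (`filter_for_network`, `build_network`,
`graph_topology`, `node_topology`, `detect_modules`, `zipi_classify`,
`random_ensemble`, `natural_connectivity`, `robustness_curve`).
Spearman |rho| > 0.6 / FDR q < 0.01 networks on the 300 most abundant
OTUs present in ≥50% of samples; full node- and graph-level topology;
Louvain modules; Zi–Pi keystone classification (hubs and connectors at
Zi 2.5 / Pi 0.62); 1000-replicate Erdős–Rényi baselines; and natural
connectivity robustness under node removal.

**Synthetic ground truth** (`simulate_dataset` and friends). Yule trees
with Brownian traits, log-normal metacommunities, and local communities
assembled under neutral Moran dynamics, Gaussian niche selection, or
region-restricted source pools — so every estimator above can be tested
against data whose generating process is known.

`run_pipeline()` orchestrates all stages for the overall sample set and
per vegetation zone, writing TSV/JSON outputs and a GraphML export per
network.

## Worked example

```r
library(ecoassembly)

ds  <- simulate_dataset("neutral", n_otus = 300, n_samples = 48,
                        n_individuals = 1000, m = 0.5, seed = 7)
fit <- fit_ncm(ds$table, n_boot = 200, seed = 8)
fit
#> Sloan neutral community model fit
#>   N = 1000 (depth), m = 0.6891 [0.6091, 0.7863], R^2 = 0.9144
#>   OTU partition: 4 below / 253 neutral / 43 above the prediction band
```

The model explains 91% of the occupancy–abundance relationship and most
OTUs sit inside the neutral prediction band, as they should for data
generated by neutral dynamics. The fitted migration rate sits somewhat
above the simulated 0.5 — the occupancy estimator's known
detection-limit bias, discussed in the methods vignette — which is why
*m* is best read comparatively across datasets.

```r
sub <- otu_table(unclass(ds$table)[1:24, ])
sub <- otu_table(unclass(sub)[, colSums(sub) > 0])
bn  <- beta_nti(sub, ds$tree, n_null = 199, seed = 9)
rc  <- raup_crick_bray(sub, n_null = 199, seed = 10)
partition_processes(bn$bnti, rc)
#> Assembly-process partition over 276 pairwise comparisons
#>   variable_selection           0  (0.0%)
#>   homogeneous_selection       11  (4.0%)
#>   dispersal_limitation         0  (0.0%)
#>   homogenizing_dispersal       6  (2.2%)
#>   undominated                259  (93.8%)
#>   determinism 4.0% / stochasticity 96.0%
```

The partition attributes 96% of pairwise comparisons to stochastic
processes — drift dominates, with no variable selection and no
dispersal limitation — matching the neutral generating process.
Selection and dispersal regimes are recovered the same way when data
are simulated with `"variable_selection"` or `"dispersal_limited"`
(see `tests/testthat/test-acceptance.R`).

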