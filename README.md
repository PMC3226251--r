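# assaynet

Network analysis of high-throughput chemical-screening campaigns, for
computational biologists asking whether the protein targets chosen for
screening are promising future drug targets.

A screening campaign is a bipartite network: bioassays on one side, the
compounds active in them on the other.  `assaynet` builds that network,
projects it onto assays by connecting any two that share at least 10% of
their active compounds (Jaccard coefficient
`J = |A ∩ B| / |A ∪ B| ≥ 0.10`), and characterizes the projection with the
standard topology diagnostics: a log-log regression on the degree
distribution `P(k)` (the scale-free test) and the clustering profile
`C_i = 2 n_i / [k_i (k_i − 1)]` (flat `C(k)` means non-hierarchical).

The second half of the package works in a protein–protein interaction
(PPI) network.  It tests whether bioassay target proteins cluster around
essential genes, approved drug targets and disease genes — comparing the
mean fraction of targets per shortest-path shell around real seeds against
10,000 randomized control proteins, with per-distance Wilcoxon rank-sum
p-values — and prioritizes bioassay targets as drug-target candidates via a
Coulomb-style *characteristic distance*: treating each essential gene as a
unit charge, the field at a candidate is `E = Σ_i f_i / d_i²` (with `f_i`
the fraction of the charged set at distance `d_i`) and `d̂ = E^(−1/2)`.
Candidates are binned by `d̂` to essential genes (ascending, width 0.5),
ranked within bins by `d̂` to drug targets (descending — novelty first),
and filtered to PPI degree ≥ 17.

A synthetic-data module (preferential-attachment interactome, marker sets
with a planted proximity signal, clustered activity tables) makes the whole
pipeline testable without any external database.

## Worked example

```r
library(assaynet)

cfg     <- synthetic_config(rng_seed = 1)      # 2000-protein study conditions
ppi     <- gen_ppi(cfg$n_proteins, cfg$attach_m, cfg$rng_seed)
markers <- gen_markers(ppi, cfg)               # essential genes are hubs;
                                               # bioassay targets planted near them
enrichment(ppi, markers$essential, markers$bioassay_targets,
           n_random = 1000, rng_seed = 1)
#> Marker enrichment around 244 seeds vs 1000 random trials
#>  distance mean_fraction random       p
#>         1        0.0137 0.0126 0.01030
#>         2        0.0144 0.0145 0.44900
#>         3        0.0139 0.0137 0.69700
#>         4        0.0103 0.0109 0.00459
#>         5        0.0033 0.0039 0.00622
#>         6        0.0000 0.0000 0.65600
```

At distance 1, 1.37% of a seed's neighbors are bioassay targets versus
1.26% around random proteins (p = 0.01): the planted clustering of targets
around essential genes is recovered.  Rows 4–5 show the complementary
depletion — mass pulled to distance 1 is missing from the outer shells.

The ranking rule applied to the bundled table of published
characteristic distances reproduces its printed top-10 order:

```r
prioritize(published_target_distances())[1:3, ]
#>      gene d_essential d_drug degree bin_index rank
#> 1 SULT1E1      1.4744 5.1837     17         2    1
#> 2    WEE1      1.3499 3.1641     47         2    2
#> 3    RGS7      1.3440 3.0462     20         2    3
```

SULT1E1 leads because its bin (`d̂_E ∈ [1.0, 1.5)`, closest to the
essential-gene field) is traversed first and it is farthest from already
drugged space (`d̂_D = 5.18`) within that bin.

## Analysis workflow

The `analysis/` scripts run the full study over synthetic inputs, writing
tables and GraphML (Cytoscape-loadable) networks under `results/`:

```sh
Rscript analysis/01_simulate.R    # interactome, marker sets, activity table
Rscript analysis/02_project.R     # bipartite network, summary, Jaccard projection
Rscript analysis/03_topology.R    # degree distribution, power-law fit, clustering
Rscript analysis/04_enrichment.R  # shells around essential/drug/disease seeds
Rscript analysis/05_prioritize.R  # characteristic distances, binned ranking
```

The same stages are callable in one step via `run_pipeline()`.  See
`vignettes/assaynet-methods.Rmd` for the model assumptions, parameter
defaults, and known desk-scale limitations.

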