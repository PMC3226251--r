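#!/usr/bin/env Rscript
# Stage 4: are bioassay targets clustered around essential genes, drug
# targets and disease genes in the interactome?
#
# For each seed set, the mean fraction of bioassay targets per shortest-path
# shell is compared against uniformly drawn control proteins, with a
# two-sided rank-sum p per distance.

library(assaynet)

data_dir <- "results/data"
ppi <- read_edges(file.path(data_dir, "ppi_edges.tsv"))
sets <- list(essential = read_marker_set(file.path(data_dir, "essential.txt")),
             drug_targets = read_marker_set(file.path(data_dir,
                                                      "drug_targets.txt")),
             disease_genes = read_marker_set(file.path(data_dir,
                                                       "disease_genes.txt")))
bt <- map_symbols(read_marker_set(file.path(data_dir,
                                            "bioassay_targets.txt")),
                  ppi)$mapped

rows <- do.call(rbind, lapply(names(sets), function(nm) {
  seeds <- map_symbols(sets[[nm]], ppi)$mapped
  er <- enrichment(ppi, seeds, bt, n_random = 1000, rng_seed = 1)
  cat(sprintf("\n== bioassay targets around %s (%d seeds) ==\n",
              nm, er$n_seeds))
  print(er)
  data.frame(seed_set = nm, distance = er$distances,
             mean_fraction = er$mean_fraction,
             random_mean_fraction = er$random_mean_fraction,
             p_value = er$p_value)
}))
write_table(rows, "results/enrichment.tsv")

cdf_bt <- degree_cdf(ppi, bt)
cdf_dt <- degree_cdf(ppi, map_symbols(sets$drug_targets, ppi)$mapped)
p_deg <- ranksum(igraph::degree(ppi, bt),
                 igraph::degree(ppi, map_symbols(sets$drug_targets,
                                                 ppi)$mapped))
cat(sprintf("\nmedian-degree comparison bioassay targets vs drug targets: p = %.3g\n",
            p_deg))
write_table(data.frame(k = as.integer(names(cdf_bt)),
                       pct_bioassay_targets = cdf_bt,
                       pct_drug_targets = cdf_dt),
            "results/degree_cdf.tsv")
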