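#!/usr/bin/env Rscript
# Stage 3: topology diagnostics of the assay network.
#
# Degree distribution with a log-log power-law fit (the scale-free
# diagnostic) and the clustering-coefficient profile (flat C(k) means the
# network is not hierarchical).

library(assaynet)

assay_net <- read_graphml("results/assay_network.graphml")

dist <- degree_distribution(assay_net)
write_table(as.data.frame(dist), "results/degree_distribution.tsv")
fit <- tryCatch(fit_power_law(dist), error = function(e) NULL)
if (is.null(fit)) {
  cat("too few positive-degree support points for a power-law fit\n")
} else {
  cat("assay network (50 nodes; too few degree classes for a meaningful tail):\n")
  print(fit)
}

# the scale-free diagnostic is informative on the interactome, whose
# preferential-attachment growth has a genuine heavy tail
ppi <- read_edges("results/data/ppi_edges.tsv")
cat("interactome:\n")
print(fit_power_law(degree_distribution(ppi)))

prof <- clustering_profile(assay_net)
cat(sprintf("clustering coefficient: mean %.2f (sd %.2f) over %d nodes\n",
            prof$overall_mean, prof$overall_sd,
            length(prof$per_node)))
if (nrow(prof$by_degree) >= 3) {
  ck <- stats::lm(log10(mean_c) ~ log10(k),
                  data = prof$by_degree[prof$by_degree$mean_c > 0, ])
  cat(sprintf("C(k) log-log slope %.2f (0 = flat/non-hierarchical, -1 = hierarchical)\n",
              stats::coef(ck)[2]))
}
write_table(prof$by_degree, "results/clustering_by_degree.tsv")
cat(sprintf("diameter of the largest component: %d\n",
            net_diameter(assay_net)))

rows <- data.frame(
  metric = c("n_nodes", "n_edges", "power_law_exponent", "power_law_r",
             "power_law_r2", "clustering_mean", "clustering_sd",
             "diameter"),
  value = c(igraph::vcount(assay_net), igraph::ecount(assay_net),
            if (is.null(fit)) NA else fit$exponent,
            if (is.null(fit)) NA else fit$pearson_r,
            if (is.null(fit)) NA else fit$r_squared,
            prof$overall_mean, prof$overall_sd, net_diameter(assay_net)))
write_table(rows, "results/topology.tsv")
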