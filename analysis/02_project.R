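#!/usr/bin/env Rscript
# Stage 2: bipartite network and Jaccard projection.
#
# Reads the stage-1 activity table, builds the bioassay-compound bipartite
# network, reports the activity means, extracts a degree-window subnetwork
# (the "zoomed" view of the campaign's mid-degree core), and projects onto
# assays connecting any two that share at least 10% active compounds.

library(assaynet)

data_dir <- "results/data"
out <- "results"
activity <- read_activity(file.path(data_dir, "activity.tsv"),
                          file.path(data_dir, "assays.tsv"))

bip <- build_bipartite(activity)
s <- summarize_bipartite(bip)
print(s)
write_table(data.frame(n_pairs = s$n_pairs,
                       n_assays_active = s$n_assays_active,
                       n_active_compounds = s$n_active_compounds,
                       mean_compounds_per_assay = s$mean_compounds_per_assay,
                       mean_assays_per_compound = s$mean_assays_per_compound),
            file.path(out, "bipartite_summary.tsv"))

sub <- extract_subnetwork(bip, assay_deg = c(20, 40), compound_deg = c(2, 10))
cat(sprintf("degree-window subnetwork: %d nodes (%d assays), %d links\n",
            igraph::vcount(sub), sum(!igraph::V(sub)$type),
            igraph::ecount(sub)))
write_graphml(sub, file.path(out, "bipartite_subnetwork.graphml"))

assay_net <- project(bip, min_jaccard = 0.10)
cat(sprintf("assay network at Jaccard >= 0.10: %d nodes, %d edges\n",
            igraph::vcount(assay_net), igraph::ecount(assay_net)))
write_graphml(assay_net, file.path(out, "assay_network.graphml"))
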