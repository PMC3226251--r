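#!/usr/bin/env Rscript
# Stage 1: generate the synthetic study inputs.
#
# Emulates a public screening snapshot at desk scale: a 2,000-protein
# preferential-attachment interactome, marker sets (essential genes biased
# toward hubs, uniform drug targets and disease genes, bioassay targets
# planted near essential genes at odds rho = 10), and a clustered
# bioassay-compound activity table.  Everything is written as the TSV
# formats the later stages read back, so the whole workflow round-trips
# through files.

library(assaynet)

out <- "results/data"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

cfg <- synthetic_config(rng_seed = 1)
ppi <- gen_ppi(cfg$n_proteins, cfg$attach_m, cfg$rng_seed)
markers <- gen_markers(ppi, cfg)
activity <- gen_activity(cfg, markers)

write_edges(ppi, file.path(out, "ppi_edges.tsv"))
write_activity(activity, file.path(out, "activity.tsv"),
               file.path(out, "assays.tsv"))
for (ms in names(markers))
  write_marker_set(markers[[ms]], file.path(out, paste0(ms, ".txt")))

cat(sprintf("interactome: %d proteins, %d interactions, mean degree %.1f\n",
            igraph::vcount(ppi), igraph::ecount(ppi),
            mean(igraph::degree(ppi))))
cat(sprintf("marker sets: %d essential, %d drug targets, %d disease, %d bioassay targets\n",
            length(markers$essential), length(markers$drug_targets),
            length(markers$disease_genes), length(markers$bioassay_targets)))
print(activity)
cat("inputs written under", out, "\n")
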