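#!/usr/bin/env Rscript
# Generate the synthetic proximity-biotinylation experiment that the rest of
# the analysis consumes: a proteinGroups-dialect table over the 6-condition x
# 3-replicate layout with planted raft residents, activation responders and
# condition-exclusive proteins, plus the ground-truth table for scoring.

library(raftquant)

out_dir <- "results/synthetic"
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

params <- simulation_params(n_proteins = 2000L, seed = 1L)
sim <- simulate_experiment(params)

write_protein_groups(sim$table, file.path(out_dir, "proteinGroups.tsv"))
write_design(sim$design, file.path(out_dir, "design.tsv"))
write.table(sim$truth, file.path(out_dir, "ground_truth.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

cat(sprintf("simulated %d proteins (+%d contaminant/decoy spike-ins)\n",
            params$n_proteins, nrow(sim$table) - params$n_proteins))
print(table(sim$truth$class))
cat(sprintf("overall missingness: %.1f%% of cells\n",
            100 * mean(table_intensities(sim$table) == 0)))
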