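#!/usr/bin/env Rscript
# Identification filtering and preprocessing: remove decoys/contaminants and
# proteins with <2 unique peptides, log2-transform, drop proteins missing in
# more than 6 of 18 samples, impute the rest by 10-nearest-neighbour
# averaging and quantile-normalize. Writes the complete matrix with its
# observed/imputed provenance mask.

library(raftquant)

design <- read_design("results/synthetic/design.tsv")
table <- read_protein_groups("results/synthetic/proteinGroups.tsv", design)
cat(sprintf("input rows: %d\n", nrow(table)))

identified <- filter_identified(table, min_unique_peptides = 2)
cat(sprintf("identified (non-decoy, non-contaminant, >=2 unique peptides): %d\n",
            nrow(identified)))
write_protein_groups(identified, "results/synthetic/identified.tsv")

m <- log_transform(identified)
m <- filter_missingness(m, max_missing = 6)
cat(sprintf("retained after missingness filter (<=6 of 18 missing): %d\n",
            nrow(m$values)))
n_missing <- sum(is.na(m$values))
m <- knn_impute(m, k = 10)
m <- quantile_normalize(m)
cat(sprintf("imputed %d cells (%.2f%% of the filtered matrix)\n",
            n_missing, 100 * n_missing / length(m$values)))

out <- data.frame(protein_id = rownames(m$values), m$values,
                  check.names = FALSE)
write.table(out, "results/synthetic/normalized_log2_matrix.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
prov <- data.frame(protein_id = rownames(m$values),
                   ifelse(m$imputed, "imputed", "observed"),
                   check.names = FALSE)
names(prov)[-1] <- colnames(m$values)
write.table(prov, "results/synthetic/provenance_mask.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
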