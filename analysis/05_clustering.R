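#!/usr/bin/env Rscript
# Temporal clustering of the significant proteins' per-time-point log2
# fold-change profiles: cluster-count selection by internal validity
# (silhouette, Dunn, connectivity) followed by k-means at the selected k.

library(raftquant)

rows <- read.delim("results/synthetic/differential.tsv")
sig <- call_significant(rows)
fc <- fc_profile_matrix(rows, sig$union)
cat(sprintf("clustering %d significant proteins over %d time points\n",
            nrow(fc), ncol(fc)))

sel <- select_k(fc, k_range = 2:30, seed = 1L)
cat("validity indices per candidate k:\n")
print(sel$validity, row.names = FALSE)
cat(sprintf("silhouette-optimal k = %d\n", sel$k_star))

res <- kmeans_profiles(fc, sel$k_star, seed = 1L)
write.table(data.frame(protein_id = names(res$cluster),
                       cluster = res$cluster),
            "results/synthetic/cluster_assignments.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(data.frame(cluster = seq_len(res$k), res$centroids,
                       check.names = FALSE),
            "results/synthetic/cluster_centroids.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(sel$validity, "results/synthetic/cluster_validity.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
cat("cluster sizes:\n")
print(table(res$cluster))
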