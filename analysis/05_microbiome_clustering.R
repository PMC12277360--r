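#!/usr/bin/env Rscript
# Stage 5 — community clustering: rarefaction, diversity, distances,
# optimal-k consensus and divide-and-compare subclustering.
#
# Rarefies the genus table to 1391 reads, computes alpha diversity and the
# generalized UniFrac (alpha 0.5) distance over the genus tree, selects the
# top-level cluster number by the four-index consensus, and recursively
# re-clusters each top cluster (prediction-strength and silhouette gated).

library(kscutotype)
library(ape)

counts <- read_feature_table("results/cohort/feature_table.tsv")
tree <- read.tree("results/cohort/tree.nwk")
seed <- 2026L

rare <- rarefy(counts, depth = 1391, seed = seed)
write_feature_table(rare, "results/rarefied_table.tsv")
alpha <- alpha_diversity(rare)
write.csv(cbind(sample_id = rownames(alpha), alpha),
          "results/alpha_diversity.csv", row.names = FALSE)

d <- generalized_unifrac(rare, tree, alpha = 0.5)
write_distance_matrix(d, "results/gunifrac.tsv")

ok <- optimal_k(d, seed = seed)
cat("optimal-k votes:\n"); print(ok$votes)
cat("consensus k =", ok$k, "\n")
write.csv(ok$indices, "results/cluster_indices.csv", row.names = FALSE)

top <- pam_cluster(d, ok$k)
sub <- divcom_subcluster(d, top, seed = seed)
clusters <- data.frame(sample_id = names(sub$assignment),
                       cluster = paste0("C", top$assignment),
                       subcluster = unname(sub$assignment))
write.csv(clusters, "results/clusters.csv", row.names = FALSE)

cat("subcluster sizes (NA = unclassified):\n")
print(table(clusters$subcluster, useNA = "ifany"))
cat("unclassified samples:", length(sub$unclassified), "\n")

# community separation across subclusters
keep <- !is.na(clusters$subcluster)
pm <- permanova(d[clusters$sample_id[keep], clusters$sample_id[keep]],
                clusters$subcluster[keep], n_perm = 999, seed = seed)
cat(sprintf("PERMANOVA across subclusters: pseudo-F = %.1f, p = %.3f\n",
            pm$pseudo_F, pm$p))
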