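#!/usr/bin/env Rscript
# Stage 6 — core-genus selection and group statistics.
#
# Prevalent genera are those detected in at least half of all samples; the
# core set keeps the prevalent genera whose relative abundance differs
# across the recovered subclusters (Kruskal-Wallis p < 0.05). Differential
# signals are profiled further with LDA-style effect sizes and the pairwise
# CLR/Wilcoxon heat-matrix across strata.

library(kscutotype)

rare <- read_feature_table("results/rarefied_table.tsv")
clusters <- read.csv("results/clusters.csv")
ksc <- read.csv("results/ksc_labels.csv")

keep <- !is.na(clusters$subcluster)
tab <- rare[clusters$sample_id[keep], ]
labels <- clusters$subcluster[keep]

report <- core_genus_selection(tab, labels)
jsonlite::write_json(report, "results/core_genera.json",
                     auto_unbox = TRUE, digits = NA)
cat("prevalent genera:", length(report$prevalent),
    "| core genera:", length(report$core), "\n")
cat("core set:", paste(report$core, collapse = ", "), "\n")

lefse <- lda_effect_size(tab, labels, seed = 2026L)
write.csv(lefse, "results/lda_effect_sizes.csv", row.names = FALSE)
cat("\ndiscriminating genera (LDA score >= 2):\n")
print(head(lefse, 8), row.names = FALSE)

strata <- ksc$strata[match(rownames(tab), ksc$subject_id)]
pairwise <- pairwise_differential(tab, strata, genera = report$core)
write.csv(pairwise, "results/pairwise_differential.csv", row.names = FALSE)
cat("\nsignificant strata pairs (|signed -log10 p| > 1):",
    sum(pairwise$significant), "of", nrow(pairwise), "\n")
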