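#!/usr/bin/env Rscript
# Stage 7 — cutotype prediction from the core genera and the age-group
# model from the metric panel.
#
# One-vs-rest boosted-tree models per aging group on the core-genus
# relative abundances (stratified 80/20 split, SMOTE-balanced training),
# evaluated by per-type and micro/macro ROC-AUC; plus the multiclass
# aging-group model from the six-metric panel.

library(kscutotype)

rare <- read_feature_table("results/rarefied_table.tsv")
core <- jsonlite::read_json("results/core_genera.json",
                            simplifyVector = TRUE)$core
ksc <- read.csv("results/ksc_labels.csv")
panel <- read.csv("results/metric_panel.csv")

rel <- relative_abundance(rare)[, core, drop = FALSE]
strata <- ksc$strata[match(rownames(rel), ksc$subject_id)]
models <- suppressWarnings(train_type_models(rel, strata, seed = 2026L))

aucs <- do.call(rbind, lapply(names(models), function(g) {
  tps <- setdiff(names(models[[g]]), ".summary")
  data.frame(group = g, type = tps,
             auc = vapply(tps, function(tp) models[[g]][[tp]]$auc, numeric(1)))
}))
write.csv(aucs, "results/type_model_auc.csv", row.names = FALSE)
cat("held-out one-vs-rest AUCs by aging group and type:\n")
print(aucs, row.names = FALSE)
for (g in names(models)) {
  s <- models[[g]]$.summary
  if (!is.null(s))
    cat(sprintf("%-7s micro-AUC %.3f  macro-AUC %.3f\n", g, s$micro, s$macro))
}

if (sum(!vapply(models, function(m) is.null(m$.summary), logical(1))) >= 1) {
  hm <- try(feature_importance_heatmap(models), silent = TRUE)
  if (!inherits(hm, "try-error"))
    write.csv(cbind(genus = rownames(hm), as.data.frame(hm)),
              "results/importance_zscores.csv", row.names = FALSE)
}

# aging-group model from the six metrics (wrinkle is missing for ages <= 9)
keep <- !is.na(panel$wrinkle)
x <- as.matrix(panel[keep, c("oiliness", "hydration", "tone", "elasticity",
                             "pore", "wrinkle")])
groups <- ksc$aging_group[match(panel$subject_id[keep], ksc$subject_id)]
em <- evaluate_age_model(x, groups, seed = 2026L)
cat(sprintf("\naging-group model from 6 metrics: micro-AUC %.3f, macro-AUC %.3f\n",
            em$micro, em$macro))
write.csv(data.frame(class = names(em$per_class), auc = em$per_class),
          "results/age_model_auc.csv", row.names = FALSE)
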