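#!/usr/bin/env Rscript
# Stage 1 — generate the study cohort.
#
# Draws a 300-subject synthetic cohort with the structure the downstream
# stages assume: age-declining tone and elasticity, a sebum peak around 30,
# age-flat moisture, and a microbiome with two top-level genus-profile
# clusters (Streptococcus- vs Cutibacterium-dominant) of which the first
# carries two nested subclusters. Writes the cohort tables plus the planted
# truth under results/cohort/.

library(kscutotype)

seed <- 2026L
cohort <- simulate_cohort(cohort_config(n_subjects = 300, seed = seed))
paths <- write_cohort(cohort, "results/cohort")

responses <- simulate_responses(cohort, missing_rate = 0.02, seed = seed)
write.csv(responses, "results/cohort/questionnaire.csv", row.names = FALSE)

cat("cohort of", nrow(cohort$subjects), "subjects written to results/cohort\n")
cat("age range:", paste(range(cohort$subjects$age), collapse = "-"), "\n")
cat("planted subcluster sizes:\n")
print(table(cohort$truth$subcluster))
cat("planted prevalent genera:", length(cohort$truth$prevalent_genera),
    "| planted core genera:", length(cohort$truth$core_genera), "\n")
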