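#!/usr/bin/env Rscript
# Stage 2 — score the questionnaire and tabulate the 16 skin types.
#
# Applies the published scoring rules (1-4 points per item, 2.5 for
# unanswered; axis cuts O>=27, S>=30, P>=31, W>=41 with the condition,
# mole and age bonuses) to the simulated questionnaire.

library(kscutotype)

responses <- read.csv("results/cohort/questionnaire.csv")
scored <- score_questionnaire(responses)
write.csv(scored, "results/bsti_types.csv", row.names = FALSE)

dist16 <- type_distribution(scored$label)
write.csv(dist16, "results/bsti_distribution.csv", row.names = FALSE)

cat("scored", nrow(scored), "subjects\n")
top <- dist16[order(-dist16$n), ][1:5, ]
cat("five most common types:\n")
print(top, row.names = FALSE)
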