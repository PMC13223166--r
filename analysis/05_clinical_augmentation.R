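#!/usr/bin/env Rscript
# Stage 5: clinical-variable-augmented network and conditional
# probability reports.
#
# Appends the eight discretized clinical covariates (age, menopausal
# status, CA125, HE4, FIGO stage, grade, tumor size, subtype) to the 14
# zone nodes, relearns and bootstraps the augmented structure, and
# evaluates posterior queries linking covariates to zone involvement.

suppressPackageStartupMessages(library(lnmpath))

seed <- 20260105
cohort <- read_cohort("results/cohort.csv")
lnm <- cohort[cohort$nact == 0 & lnm_positive(cohort), ]

aug <- augment_with_clinical(lnm, clinical_bn_spec(), B = 100, seed = seed)
cat(sprintf("augmented network: %d nodes, %d edges\n",
            length(aug$dag$nodes), nrow(dag_edges(aug$dag))))
write.table(edge_strength_table(aug$edges),
            "results/augmented_edge_strength.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)

clin_edges <- edge_strength_table(aug$edges, min_freq = 0.3)
clin_edges <- clin_edges[!(clin_edges$parent %in% zone_names() &
                             clin_edges$child %in% zone_names()), ]
cat("\ncovariate-zone associations with bootstrap frequency > 0.3:\n")
print(clin_edges, row.names = FALSE, digits = 2)

queries <- list(
  list(target = c(zone_05 = "1"), evidence = c(zone_03 = "1", grade = "G3")),
  list(target = c(zone_05 = "1"), evidence = c(zone_03 = "1")),
  list(target = c(zone_12 = "1"), evidence = c(zone_11 = "1")),
  list(target = c(zone_12 = "1"), evidence = c(zone_11 = "0")),
  list(target = c(zone_01 = "1"), evidence = c(zone_05 = "1", zone_03 = "1"))
)
rep_ <- conditional_probability_report(aug$dag, aug$cpts, queries)
write.table(rep_, "results/conditional_probabilities.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("\nconditional probability report:\n")
print(rep_, row.names = FALSE, digits = 3)
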