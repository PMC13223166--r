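#!/usr/bin/env Rscript
# Stage 3: regional mapping of lymph node metastasis.
#
# After excluding NACT-treated patients, computes the node-level and
# patient-level zone distributions, the overall nodal positivity rate,
# the per-zone resection summary, and the laterality-stratified
# patient-level distributions.

suppressPackageStartupMessages(library(lnmpath))

cohort <- read_cohort("results/cohort.csv")
mapped <- cohort[cohort$nact == 0, ]
cat(sprintf("mapping cohort: %d patients after NACT exclusion, %d LN-positive\n",
            nrow(mapped), sum(lnm_positive(mapped))))

nd <- node_level_distribution(mapped)
pd <- patient_level_distribution(mapped)
write.table(nd, "results/node_distribution.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(pd, "results/patient_distribution.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

cat(sprintf("overall nodal positivity: %.2f%%\n",
            100 * overall_positivity_rate(mapped)))
top3 <- head(pd[order(-pd$patient_share), ], 3)
cat("most frequently involved zones (patient-level):\n")
print(top3, row.names = FALSE, digits = 3)

rs <- resection_summary(mapped)
write.table(rs, "results/resection_summary.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat(sprintf("total nodes removed: %d\n", sum(rs$total_removed)))

strata <- stratify_by_laterality(mapped)
for (side in names(strata)) {
  sub <- strata[[side]]
  if (!any(lnm_positive(sub))) next
  psub <- patient_level_distribution(sub)
  write.table(psub, sprintf("results/patient_distribution_%s.tsv", side),
              sep = "\t", quote = FALSE, row.names = FALSE)
  cat(sprintf("%s-sided stratum: n = %d\n", side, nrow(sub)))
}
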