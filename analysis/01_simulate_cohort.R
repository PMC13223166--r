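#!/usr/bin/env Rscript
# Stage 1: generate the synthetic study cohort.
#
# The real cohort behind the published analysis is not deposited, so the
# workflow runs on a synthetic cohort with known ground truth: 654
# patients, the canonical planted routes (left iliac chain 3 -> 5 -> 1 and
# para-aortic pair 11 -> 12), the published laterality mixture and a ~19%
# NACT rate.  Every downstream stage reads the CSV written here.

suppressPackageStartupMessages(library(lnmpath))

seed <- 20260101
dir.create("results", showWarnings = FALSE)

cfg <- reference_sim_config(654, seed = seed)
cohort <- generate_cohort(cfg)
write_cohort(cohort, "results/cohort.csv")
write_edge_list(cfg$truth_dag, "results/truth_edges.tsv")

cat(sprintf("cohort: %d patients, %d (%.1f%%) LN-positive, %d NACT-treated\n",
            nrow(cohort), sum(lnm_positive(cohort)),
            100 * mean(lnm_positive(cohort)), sum(cohort$nact)))
cat("planted truth edges:\n")
print(dag_edges(cfg$truth_dag))
cat("written: results/cohort.csv, results/truth_edges.tsv\n")
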