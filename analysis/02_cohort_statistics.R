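#!/usr/bin/env Rscript
# Stage 2: cohort-level statistics.
#
# Reproduces the statistical layer of the analysis on the synthetic
# cohort: a summary table by LN status (chi-square / Mann-Whitney),
# univariate odds ratios with Woolf intervals for the dichotomized risk
# factors, and a forward stepwise logistic model.  Also recomputes, from
# the published 2x2 counts shipped with the package, the two odds ratios
# that are derivable without the raw cohort.

suppressPackageStartupMessages(library(lnmpath))

cohort <- read_cohort("results/cohort.csv")

summary_tab <- cohort_summary_table(cohort)
write.table(summary_tab, "results/cohort_summary.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

or_tab <- univariate_or_table(cohort)
write.table(or_tab, "results/univariate_or.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("univariate odds ratios (synthetic cohort):\n")
print(or_tab, digits = 3)

sig <- or_tab$variable[!is.na(or_tab$p_value) & or_tab$p_value < 0.05]
cat("\nvariables entering stepwise selection:",
    paste(sig, collapse = ", "), "\n")

# published-table check: the two cleanly derivable odds ratios
counts <- read.csv(system.file("extdata", "table1_lnm_counts.csv",
                               package = "lnmpath"))
for (v in counts$variable) {
  row <- counts[counts$variable == v, ]
  res <- odds_ratio_2x2(table2x2(row$n00, row$n01, row$n10, row$n11))
  cat(sprintf("published %s: OR %.2f (%.2f-%.2f)\n", v, res$or,
              res$ci_low, res$ci_high))
}
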