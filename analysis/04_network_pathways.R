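#!/usr/bin/env Rscript
# Stage 4: Bayesian network learning, bootstrap edge confidence,
# co-occurrence, and dual-criterion pathway extraction.
#
# On the LN-positive, NACT-excluded subset: hill-climbing structure
# search with BIC scoring, maximum-likelihood CPTs, 200 bootstrap
# resamples for edge confidence, co-occurrence ranking, and extraction of
# routes with edge strength >= 0.6 whose pairs rank in the top 30% of
# co-occurrence and are anatomically adjacent.  Since the cohort carries
# planted truth (3 -> 5 -> 1, 11 -> 12), the printed routes can be read
# against it directly.

suppressPackageStartupMessages(library(lnmpath))

seed <- 20260104
cohort <- read_cohort("results/cohort.csv")
lnm <- cohort[cohort$nact == 0 & lnm_positive(cohort), ]
zones <- lnm[, zone_names()]
cat(sprintf("network cohort: %d LN-positive patients\n", nrow(lnm)))

dag <- hill_climb(zones, seed = stage_seed(seed, "learn"))
cat(sprintf("learned structure: %d edges, BIC %.1f\n",
            nrow(dag_edges(dag)), attr(dag, "score")))
write_edge_list(dag, "results/network_edges.tsv")
cpts <- fit_cpts(dag, zones)
write_cpts_json(cpts, "results/network_cpts.json")

edges <- bootstrap_edge_strength(zones, B = 200,
                                 seed = stage_seed(seed, "bootstrap"))
write.table(edge_strength_table(edges), "results/edge_strength.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)

cooc <- cooccurrence_matrix(lnm)
write.table(round(cooc$matrix, 4), "results/cooccurrence.tsv",
            sep = "\t", quote = FALSE)
top <- top_quantile_pairs(cooc, q = 0.3)
write.table(top, "results/top_pairs.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

paths <- extract_routes(edges, top, tau = 0.6)
write.table(paths$highlighted, "results/pathways.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write_dot(paths, "results/pathways.dot")

cat("\nhighlighted metastatic routes (edge strength, co-occurrence):\n")
print(paths$highlighted, row.names = FALSE, digits = 2)
cat("\nnode roles:\n")
roles <- paths$node_labels[paths$node_labels != "isolated"]
print(roles)
cat("\nmaximal route chains:\n")
for (chain in chain_report(paths)) {
  cat("  ", paste(chain, collapse = " -> "), "\n")
}
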