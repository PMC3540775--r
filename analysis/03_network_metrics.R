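#!/usr/bin/env Rscript

# Step 3: topological network measures.
#
# Computes, per subject: characteristic path length L, clustering C, the
# benchmark-normalized ratios gamma and lambda, small-worldness sigma,
# Louvain modularity Q, and the per-node measures (degree, local clustering,
# local path length, node-wise sigma). The random benchmark uses 100 uniform
# random graphs with matched node and edge counts per subject. Prints the
# group summary battery (means +/- SD).

suppressPackageStartupMessages(library(fcnet))

cohort <- load_cohort("results/cohort/manifest.json")
conn <- cohort_connectivity(cohort, density = 0.20, remove_global = TRUE)
gm <- cohort_graph_metrics(conn, master_seed = 1L, benchmark_realizations = 100L)

utils::write.table(gm$global, "results/global_metrics.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
utils::write.table(gm$per_node, "results/node_metrics.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)

cat("Global aggregate measures (mean +/- SD):\n")
cat(sprintf("%-28s %-18s %-18s\n", "measure", "control", "case"))
for (m in c("L", "C", "gamma", "lambda", "sigma", "Q")) {
  a <- gm$global[[m]][gm$global$group == "control"]
  b <- gm$global[[m]][gm$global$group == "case"]
  cat(sprintf("%-28s %6.3f +/- %-8.3f %6.3f +/- %-8.3f\n", m,
              mean(a), sd(a), mean(b), sd(b)))
}
cat("\nHigh sigma (>1) with L near the random benchmark indicates the\n")
cat("small-world regime; Q reflects the modular community structure.\n")
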