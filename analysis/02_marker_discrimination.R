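#!/usr/bin/env Rscript
# Step 2: how well does each candidate marker discriminate on its own?
# First the motivating question — can hsCRP and 1,5-AG pick HNF1A MODY out
# of the whole cohort? — then the one-vs-rest C-statistics that drive the
# sequential tree.
#
# Reads: results/cohort.csv   Writes: results/single_marker_auc.csv

suppressMessages(library(modytree))
co <- read_cohort("results/cohort.csv")

auc_for <- function(df, target, marker) {
  y <- df$group == target
  a <- c_statistic(df[[marker]][y], df[[marker]][!y])
  a2 <- c_statistic(-df[[marker]][y], -df[[marker]][!y])
  if (a2$auc > a$auc) a <- a2
  data.frame(target = target, marker = marker, auc = a$auc,
             ci_low = a$ci_low, ci_high = a$ci_high)
}

rows <- list()
for (m in c("hscrp", "ag15")) {
  rows[[length(rows) + 1]] <- auc_for(co, "HNF1A", m)
}
for (g in c("T1D", "T2D", "HNF1A", "GCK")) {
  for (m in default_marker_pool()) {
    rows[[length(rows) + 1]] <- auc_for(co, g, m)
  }
}
tab <- do.call(rbind, rows)
write.csv(tab, "results/single_marker_auc.csv", row.names = FALSE)
print(tab, digits = 3, row.names = FALSE)

message("\nReading the table: neither HNF1A biomarker alone separates HNF1A ",
        "MODY from all other diabetes types, while C-peptide nearly perfectly ",
        "identifies type 1 diabetes — the motivation for a sequential tree ",
        "that peels off the easy groups first.")
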