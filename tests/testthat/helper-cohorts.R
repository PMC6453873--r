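# Shared fixtures, built in code.

# One record per group, every marker at its published central value
# (medians for the skewed biomarkers, means for BMI).
central_value_records <- function() {
  data.frame(
    id = c("h1", "g1", "t1", "t2"),
    group = c("HNF1A", "GCK", "T1D", "T2D"),
    sex = c("F", "F", "M", "F"),
    age = c(38.8, 34.7, 29.1, 59.4),
    diabetes_duration = c(17.3, 26.2, 12.5, 6.5),
    age_at_diagnosis = c(23.1, 7.3, 16.6, 52.9),
    bmi = c(23.9, 23.7, 23.9, 30.3),
    creatinine = c(75.5, 74.0, 74.4, 82.7),
    hba1c = c(6.9, 6.3, 7.4, 6.8),
    fasting_glucose = c(6.8, 6.9, 8.1, 7.6),
    c_peptide = c(1.45, 1.43, 0.01, 2.78),
    hscrp = c(0.51, 0.76, 0.75, 1.33),
    ag15 = c(4.70, 11.24, 3.77, 6.07),
    treatment = c("non_insulin", "diet", "insulin", "non_insulin"),
    stringsAsFactors = FALSE
  )
}

# Exhaustive tie-aware pairwise AUC: the independent oracle for c_statistic.
brute_force_auc <- function(pos, neg) {
  cmp <- outer(pos, neg, ">") + 0.5 * outer(pos, neg, "==")
  mean(cmp)
}

# Small labelled data frame for logistic / selection tests.
two_class_frame <- function(x_list, y) {
  df <- as.data.frame(x_list)
  df$id <- sprintf("r%03d", seq_len(nrow(df)))
  df$group <- ifelse(y, "T1D", "T2D")
  df
}
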