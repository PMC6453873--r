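## Applying a decision tree to a cohort: cascade classification, Fig-2
## style branch accounting, confusion matrix and per-group rates.

#' Round half up
#'
#' Decimal rounding with ties away from zero (`round()` rounds half to
#' even), matching the one-decimal percentage style of clinical reports.
#'
#' @param x numeric.
#' @param digits decimal places.
#' @return rounded values.
#' @export
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Per-group correct-classification percentage
#'
#' @param correct,total non-negative counts, `correct <= total`.
#' @return `100 * correct / total`, rounded half-up to one decimal.
#' @export
classification_rate <- function(correct, total) {
  stopifnot(all(correct >= 0), all(total > 0), all(correct <= total))
  round_half_up(100 * correct / total, 1)
}

step_fires <- function(step, scores, boundary = c("exclusive", "inclusive")) {
  boundary <- match.arg(boundary)
  t <- step$threshold
  if (step$direction == "lower_is_positive") {
    if (boundary == "exclusive") scores < t else scores <= t
  } else {
    if (boundary == "exclusive") scores > t else scores >= t
  }
}

#' Classify patient records with a decision tree
#'
#' Evaluates the tree's steps in order. At each step the record's
#' composite-index score is compared with the step threshold under the
#' step's orientation; the first step that fires assigns its target
#' group, and records that fire no step receive the remaining terminal
#' label. Every record gets exactly one label; a missing marker is an
#' error, never a silently skipped step.
#'
#' @param tree a `decision_tree` (built or [published_tree()]).
#' @param data a [cohort()] or data frame of records to classify.
#' @param boundary how a score exactly equal to a threshold is handled:
#'   `"exclusive"` (default) sends it down the non-target branch,
#'   `"inclusive"` down the target branch.
#' @return character vector of assigned group labels, one per record.
#' @export
classify <- function(tree, data, boundary = c("exclusive", "inclusive")) {
  boundary <- match.arg(boundary)
  stopifnot(inherits(tree, "decision_tree"))
  data <- as.data.frame(data)
  n <- nrow(data)
  assigned <- rep(NA_character_, n)
  alive <- rep(TRUE, n)
  for (step in tree$steps) {
    if (!any(alive)) break
    scores <- evaluate_index(step$index, data[alive, , drop = FALSE])
    fired <- step_fires(step, scores, boundary)
    idx <- which(alive)
    assigned[idx[fired]] <- step$target_group
    alive[idx[fired]] <- FALSE
  }
  leftover <- setdiff(tree$terminal_pair, tree$steps[[length(tree$steps)]]$target_group)
  assigned[alive] <- leftover
  assigned
}

#' Evaluate a decision tree on a labelled cohort
#'
#' Classifies every record (misclassified patients are retained in the
#' cascade, exactly as in clinical application), then tabulates the
#' 4x4 confusion matrix, per-group correct counts and percentages
#' (half-up, one decimal), and per-step branch tallies: how many records
#' of each true group took the target branch at each step.
#'
#' @param tree a `decision_tree`.
#' @param data a fully labelled [cohort()] carrying all tree markers.
#' @param boundary passed to [classify()].
#' @return an `evaluation_report`: list with `confusion` (true x
#'   assigned), `per_group` (data frame: group, correct, total,
#'   percentage), `overall` (correct, total, percentage) and
#'   `branch_tallies` (one matrix per step: true group x branch).
#' @export
evaluate_tree <- function(tree, data, boundary = c("exclusive", "inclusive")) {
  boundary <- match.arg(boundary)
  df <- as.data.frame(data)
  if (anyNA(df$group) || is.null(df$group)) {
    stop("evaluate_tree: every record must carry a true group label", call. = FALSE)
  }
  groups <- mody_groups()
  assigned <- classify(tree, df, boundary)

  confusion <- table(true = factor(df$group, levels = groups),
                     assigned = factor(assigned, levels = groups))
  correct <- diag(confusion)
  totals <- rowSums(confusion)
  present <- totals > 0
  pct <- rep(NA_real_, length(groups))
  pct[present] <- classification_rate(correct[present], totals[present])
  per_group <- data.frame(
    group = groups,
    correct = as.integer(correct),
    total = as.integer(totals),
    percentage = pct
  )

  tallies <- list()
  alive <- rep(TRUE, nrow(df))
  for (k in seq_along(tree$steps)) {
    step <- tree$steps[[k]]
    scores <- evaluate_index(step$index, df[alive, , drop = FALSE])
    fired <- step_fires(step, scores, boundary)
    tal <- table(true = factor(df$group[alive], levels = groups),
                 branch = factor(ifelse(fired, step$target_group, "continue"),
                                 levels = c(step$target_group, "continue")))
    tallies[[k]] <- tal
    idx <- which(alive)
    alive[idx[fired]] <- FALSE
  }
  names(tallies) <- sprintf("step_%d", seq_along(tree$steps))

  structure(list(confusion = confusion,
                 per_group = per_group,
                 overall = list(correct = sum(correct), total = nrow(df),
                                percentage = classification_rate(sum(correct), nrow(df))),
                 branch_tallies = tallies,
                 boundary = boundary),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat("<evaluation_report>\n")
  print(x$confusion)
  for (i in seq_len(nrow(x$per_group))) {
    r <- x$per_group[i, ]
    if (r$total > 0) {
      cat(sprintf("  %-6s %3d/%3d correctly classified (%.1f%%)\n",
                  r$group, r$correct, r$total, r$percentage))
    }
  }
  cat(sprintf("  overall %d/%d (%.1f%%)\n", x$overall$correct,
              x$overall$total, x$overall$percentage))
  invisible(x)
}
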