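## Greedy construction of the sequential decision tree: at each stage find
## the group best discriminated one-vs-rest by a C-statistic-gated forward
## marker selection, freeze a composite index and Youden threshold for it,
## peel that group's records off, and repeat until two groups remain.

#' Default candidate marker pool for tree building
#'
#' The five candidate disease markers considered by the tree builder:
#' 1,5-AG, hsCRP, BMI, fasting glucose and fasting serum C-peptide.
#' @return character vector of marker column names.
#' @export
default_marker_pool <- function() {
  c("ag15", "hscrp", "bmi", "fasting_glucose", "c_peptide")
}

oriented_auc <- function(scores, y) {
  a <- c_statistic(scores[y], scores[!y])
  if (a$auc >= 0.5) {
    list(auc = a, direction = "higher_is_positive", oriented = scores)
  } else {
    list(auc = c_statistic(-scores[y], -scores[!y]),
         direction = "lower_is_positive", oriented = -scores)
  }
}

#' Forward marker selection gated by paired C-statistic tests
#'
#' Starts from the single marker with the best orientation-corrected
#' C-statistic for the target group (one vs the rest), then repeatedly
#' refits a logistic model with each remaining pool marker added and
#' accepts the addition with the largest C-statistic gain, provided its
#' DeLong paired test against the current model is significant at
#' `alpha`. Candidates whose fit hits separation or a singular design are
#' skipped with a warning. Selection stops when no addition qualifies.
#'
#' @param data labelled records (a [cohort()] view) still in play.
#' @param target group label to discriminate from the rest.
#' @param pool candidate marker column names.
#' @param alpha significance gate for retaining an added marker.
#' @return list with `markers` (in order of selection), `fit` (the
#'   logistic fit, or `NULL` for a single marker whose fit is separated),
#'   `index` (the resulting [composite_index()]), `auc` (an `auc_result`
#'   for the oriented index scores) and `scores` (oriented scores, higher
#'   = more like the target).
#' @export
forward_select_markers <- function(data, target, pool, alpha = 0.05) {
  if (length(pool) == 0) stop("forward_select_markers: empty pool", call. = FALSE)
  data <- as.data.frame(data)
  y <- data$group == target
  if (!any(y)) stop("forward_select_markers: target group absent", call. = FALSE)
  pool <- sort(unique(pool))  # alphabetical tie-break, order-invariant

  singles <- lapply(pool, function(m) oriented_auc(data[[m]], y))
  names(singles) <- pool
  aucs <- vapply(singles, function(s) s$auc$auc, numeric(1))
  lead <- pool[which.max(aucs)]  # which.max: first (alphabetical) on ties
  selected <- lead
  current <- singles[[lead]]
  current_scores <- current$oriented
  current_fit <- NULL

  repeat {
    remaining <- setdiff(pool, selected)
    if (length(remaining) == 0) break
    cands <- list()
    for (m in remaining) {
      fit <- tryCatch(fit_logistic(data, c(selected, m), y),
                      error = function(e) {
                        warning("candidate {", paste(c(selected, m), collapse = ", "),
                                "} skipped: ", conditionMessage(e), call. = FALSE)
                        NULL
                      })
      if (is.null(fit)) next
      sc <- linear_predictor(fit, data)
      a <- c_statistic(sc[y], sc[!y])
      gain <- a$auc - c_statistic(current_scores[y], current_scores[!y])$auc
      if (gain <= 0) next
      test <- tryCatch(delong_paired_test(sc, current_scores, y),
                       error = function(e) NULL)
      if (is.null(test) || test$p >= alpha) next
      cands[[m]] <- list(fit = fit, scores = sc, auc = a, gain = gain)
    }
    if (length(cands) == 0) break
    gains <- vapply(cands, function(cc) cc$gain, numeric(1))
    pick <- names(cands)[which.max(gains)]
    selected <- c(selected, pick)
    current_fit <- cands[[pick]]$fit
    current_scores <- cands[[pick]]$scores
  }

  if (is.null(current_fit) && length(selected) == 1) {
    current_fit <- tryCatch(fit_logistic(data, selected, y), error = function(e) NULL)
  }
  index <- if (!is.null(current_fit)) {
    index_from_fit(current_fit)
  } else {
    ## perfectly separating single marker: weight-1 index oriented by AUC
    composite_index(selected, 1, direction = singles[[selected]]$direction)
  }
  idx_scores <- evaluate_index(index, data)
  oriented <- if (index$direction == "higher_is_positive") idx_scores else -idx_scores
  list(markers = selected, fit = current_fit, index = index,
       auc = c_statistic(oriented[y], oriented[!y]), scores = oriented)
}

#' Build the sequential group-peeling decision tree
#'
#' While more than two groups remain, runs [forward_select_markers()]
#' one-vs-rest for every remaining group, targets the group with the
#' highest selected-set C-statistic (ties: smaller marker set, then the
#' fixed group order T1D, T2D, HNF1A, GCK), freezes that group's
#' composite index with its Youden threshold, and removes the group's
#' records. The last step's index splits the final two groups, which both
#' become leaves. The build is deterministic given the cohort and
#' configuration.
#'
#' @param data a labelled [cohort()] with at least 3 groups, each of at
#'   least 10 records.
#' @param pool candidate marker names (default: 1,5-AG, hsCRP, BMI,
#'   fasting glucose, C-peptide).
#' @param alpha significance gate passed to the forward selection.
#' @return a `decision_tree`: list of steps (target group, index with
#'   threshold, direction, `auc_result`), the terminal pair, and the
#'   candidate pool.
#' @export
build_tree <- function(data, pool = default_marker_pool(), alpha = 0.05) {
  df <- as.data.frame(data)
  if (anyNA(df$group)) stop("build_tree: all records must be labelled", call. = FALSE)
  groups_left <- intersect(mody_group_priority(), unique(df$group))
  if (length(groups_left) < 3) {
    stop("build_tree: need at least 3 groups", call. = FALSE)
  }
  steps <- list()
  repeat {
    sizes <- table(factor(df$group, levels = groups_left))
    if (any(sizes < 10)) {
      stop("build_tree small-sample error: group(s) ",
           paste(names(sizes)[sizes < 10], collapse = ", "),
           " have fewer than 10 records at step ", length(steps) + 1, call. = FALSE)
    }
    final_step <- length(groups_left) == 2
    targets <- if (final_step) groups_left[1] else groups_left
    fits <- lapply(targets, function(g) forward_select_markers(df, g, pool, alpha))
    names(fits) <- targets
    aucs <- vapply(fits, function(f) f$auc$auc, numeric(1))
    sizes_sel <- vapply(fits, function(f) length(f$markers), integer(1))
    best_auc <- max(aucs)
    if (best_auc <= 0.5 + 1e-6) {
      stop("build_tree degenerate-discrimination error: best C-statistic ",
           sprintf("%.3f", best_auc), " at step ", length(steps) + 1, call. = FALSE)
    }
    tied <- which(aucs >= best_auc - 1e-12)
    tied <- tied[sizes_sel[tied] == min(sizes_sel[tied])]
    target <- targets[tied[1]]  # targets already in fixed priority order
    sel <- fits[[target]]

    y <- df$group == target
    curve_dir <- if (sel$index$direction == "higher_is_positive") "higher" else "lower"
    idx_scores <- evaluate_index(sel$index, df)
    curve <- roc_curve(idx_scores, y, direction = curve_dir)
    thr <- select_threshold(curve, "youden")
    index <- sel$index
    index$threshold <- thr$threshold
    steps[[length(steps) + 1]] <- list(
      target_group = target,
      index = index,
      threshold = thr$threshold,
      direction = index$direction,
      sensitivity = thr$sensitivity,
      specificity = thr$specificity,
      auc = sel$auc,
      n_remaining = nrow(df)
    )
    if (final_step) {
      terminal_pair <- c(target, setdiff(groups_left, target))
      break
    }
    df <- df[!y, , drop = FALSE]
    groups_left <- setdiff(groups_left, target)
  }
  structure(list(steps = steps, terminal_pair = terminal_pair,
                 candidate_markers = sort(unique(pool)), alpha = alpha),
            class = "decision_tree")
}

#' The published three-step decision tree
#'
#' Step 1 assigns type 1 diabetes when fasting C-peptide falls below
#' 0.6 ng/ml; step 2 assigns type 2 diabetes when
#' `C-peptide + 0.16 x BMI` exceeds 6.29; step 3 assigns HNF1A MODY when
#' `1,5-AG + 1.56 x hsCRP` falls below 10.16, and GCK MODY otherwise.
#'
#' @return a `decision_tree` with the published indices and thresholds.
#' @export
published_tree <- function() {
  steps <- list(
    list(target_group = "T1D",
         index = composite_index("c_peptide", 1, "lower_is_positive", threshold = 0.6),
         threshold = 0.6, direction = "lower_is_positive",
         sensitivity = NA_real_, specificity = NA_real_, auc = NULL,
         n_remaining = NA_integer_),
    list(target_group = "T2D",
         index = composite_index(c("c_peptide", "bmi"), c(1, 0.16),
                                 "higher_is_positive", threshold = 6.29),
         threshold = 6.29, direction = "higher_is_positive",
         sensitivity = NA_real_, specificity = NA_real_, auc = NULL,
         n_remaining = NA_integer_),
    list(target_group = "HNF1A",
         index = composite_index(c("ag15", "hscrp"), c(1, 1.56),
                                 "lower_is_positive", threshold = 10.16),
         threshold = 10.16, direction = "lower_is_positive",
         sensitivity = NA_real_, specificity = NA_real_, auc = NULL,
         n_remaining = NA_integer_)
  )
  structure(list(steps = steps, terminal_pair = c("HNF1A", "GCK"),
                 candidate_markers = default_marker_pool(), alpha = 0.05),
            class = "decision_tree")
}

#' @export
print.decision_tree <- function(x, ...) {
  cat(sprintf("<decision_tree> %d step(s); terminal pair %s/%s\n",
              length(x$steps), x$terminal_pair[1], x$terminal_pair[2]))
  for (k in seq_along(x$steps)) {
    s <- x$steps[[k]]
    terms <- c(s$index$markers[1],
               if (length(s$index$markers) > 1)
                 sprintf("%.3g x %s", s$index$weights[-1], s$index$markers[-1]))
    rel <- if (s$direction == "lower_is_positive") "<" else ">"
    auc_txt <- if (!is.null(s$auc)) sprintf(" [C-statistic %.3f]", s$auc$auc) else ""
    cat(sprintf("  step %d: %s %s %g -> %s%s\n", k,
                paste(terms, collapse = " + "), rel, s$threshold,
                s$target_group, auc_txt))
  }
  invisible(x)
}

#' Serialize a decision tree to JSON
#' @param tree a `decision_tree`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_tree <- function(tree, path) {
  stopifnot(inherits(tree, "decision_tree"))
  steps <- lapply(tree$steps, function(s) {
    out <- list(target_group = s$target_group,
                markers = as.list(s$index$markers),
                weights = as.list(s$index$weights),
                threshold = s$threshold,
                direction = s$direction)
    if (!is.null(s$auc)) {
      out$auc <- list(auc = s$auc$auc, variance = s$auc$variance,
                      ci_low = s$auc$ci_low, ci_high = s$auc$ci_high,
                      n_pos = s$auc$n_pos, n_neg = s$auc$n_neg)
    }
    out
  })
  obj <- list(format = "modytree/decision_tree", version = 1L,
              steps = steps,
              terminal_pair = as.list(tree$terminal_pair),
              candidate_markers = as.list(tree$candidate_markers),
              alpha = tree$alpha)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a decision tree from JSON
#' @param path path to a JSON file written by [write_tree()] (the
#'   published tree ships under `inst/extdata/published_tree.json`).
#' @return a `decision_tree`.
#' @export
read_tree <- function(path) {
  obj <- jsonlite::read_json(path)
  steps <- lapply(obj$steps, function(s) {
    idx <- composite_index(unlist(s$markers), unlist(s$weights),
                           direction = s$direction, threshold = s$threshold)
    auc <- NULL
    if (!is.null(s$auc)) {
      auc <- structure(list(auc = s$auc$auc, variance = s$auc$variance,
                            ci_low = s$auc$ci_low, ci_high = s$auc$ci_high,
                            n_pos = s$auc$n_pos, n_neg = s$auc$n_neg),
                       class = "auc_result")
    }
    list(target_group = s$target_group, index = idx,
         threshold = s$threshold, direction = s$direction,
         sensitivity = NA_real_, specificity = NA_real_, auc = auc,
         n_remaining = NA_integer_)
  })
  structure(list(steps = steps,
                 terminal_pair = unlist(obj$terminal_pair),
                 candidate_markers = unlist(obj$candidate_markers),
                 alpha = obj$alpha),
            class = "decision_tree")
}
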