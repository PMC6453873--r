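## C-statistic, DeLong variance and paired AUC comparison.
##
## The C-statistic is the tie-aware Mann-Whitney probability
##   AUC = P(score_pos > score_neg) + 0.5 P(score_pos = score_neg),
## estimated by counting over all (positive, negative) pairs. Variance and
## the paired test follow DeLong's structural components: for positive i,
## V10_i is the mean placement of i against all negatives (ties half), and
## symmetrically V01_j for negatives; then
##   var(AUC) = var(V10)/n_pos + var(V01)/n_neg,
## and for two scores on the same subjects the covariance of the two
## component sets gives the variance of the AUC difference.

delong_placements <- function(scores_pos, scores_neg) {
  cmp <- outer(scores_pos, scores_neg, ">") + 0.5 * outer(scores_pos, scores_neg, "==")
  list(v10 = rowMeans(cmp), v01 = 1 - colMeans(cmp), auc = mean(cmp))
}

#' Tie-aware C-statistic with DeLong variance and 95% CI
#'
#' @param scores_pos scores of the positive class (higher = more positive).
#' @param scores_neg scores of the negative class.
#' @param conf_level confidence level for the Wald interval on the AUC
#'   scale (clipped to `[0, 1]`).
#' @return an `auc_result`: list with `auc`, `variance`, `ci_low`,
#'   `ci_high`, `n_pos`, `n_neg`.
#' @export
c_statistic <- function(scores_pos, scores_neg, conf_level = 0.95) {
  scores_pos <- as.numeric(scores_pos)
  scores_neg <- as.numeric(scores_neg)
  if (length(scores_pos) == 0 || length(scores_neg) == 0) {
    stop("c_statistic domain error: both classes must be non-empty", call. = FALSE)
  }
  if (anyNA(scores_pos) || anyNA(scores_neg)) {
    stop("c_statistic domain error: scores contain missing values", call. = FALSE)
  }
  pl <- delong_placements(scores_pos, scores_neg)
  m <- length(scores_pos)
  n <- length(scores_neg)
  variance <- (if (m > 1) stats::var(pl$v10) / m else 0) +
    (if (n > 1) stats::var(pl$v01) / n else 0)
  half <- stats::qnorm(1 - (1 - conf_level) / 2) * sqrt(variance)
  structure(list(auc = pl$auc, variance = variance,
                 ci_low = max(0, pl$auc - half), ci_high = min(1, pl$auc + half),
                 n_pos = m, n_neg = n),
            class = "auc_result")
}

#' @export
print.auc_result <- function(x, ...) {
  cat(sprintf("C-statistic %.3f (95%% CI %.3f, %.3f); n_pos = %d, n_neg = %d\n",
              x$auc, x$ci_low, x$ci_high, x$n_pos, x$n_neg))
  invisible(x)
}

#' DeLong test for two paired (correlated) AUCs
#'
#' Compares the C-statistics of two score vectors measured on the same
#' subjects, using the covariance of their DeLong structural components.
#'
#' @param scores_a,scores_b numeric scores per subject (same subjects,
#'   same order; higher = more positive for both).
#' @param labels logical or 0/1 vector marking the positive class.
#' @return list with `auc_a`, `auc_b`, `z`, `p` (two-sided). A degenerate
#'   zero-variance difference is reported as `p = 1` when the AUCs are
#'   equal and is an error otherwise.
#' @export
delong_paired_test <- function(scores_a, scores_b, labels) {
  labels <- as.logical(labels)
  if (length(scores_a) != length(labels) || length(scores_b) != length(labels)) {
    stop("delong_paired_test: scores and labels must have equal length", call. = FALSE)
  }
  if (!any(labels) || all(labels)) {
    stop("delong_paired_test domain error: both classes must be present", call. = FALSE)
  }
  pa <- delong_placements(scores_a[labels], scores_a[!labels])
  pb <- delong_placements(scores_b[labels], scores_b[!labels])
  m <- sum(labels)
  n <- sum(!labels)
  s10 <- stats::cov(cbind(pa$v10, pb$v10))
  s01 <- stats::cov(cbind(pa$v01, pb$v01))
  var_diff <- (s10[1, 1] + s10[2, 2] - 2 * s10[1, 2]) / m +
    (s01[1, 1] + s01[2, 2] - 2 * s01[1, 2]) / n
  d <- pa$auc - pb$auc
  if (var_diff <= .Machine$double.eps) {
    if (abs(d) <= 1e-12) {
      return(list(auc_a = pa$auc, auc_b = pb$auc, z = 0, p = 1))
    }
    stop("delong_paired_test: zero variance of AUC difference with unequal AUCs",
         call. = FALSE)
  }
  z <- d / sqrt(var_diff)
  list(auc_a = pa$auc, auc_b = pb$auc, z = z, p = 2 * stats::pnorm(-abs(z)))
}

#' ROC curve over unique score cutpoints
#'
#' Builds the stepwise sensitivity/specificity curve. A subject is called
#' positive when its score lies on the positive side of the cutpoint,
#' inclusive: `score >= t` for `direction = "higher"`, `score <= t` for
#' `direction = "lower"`. The threshold grid is the set of unique observed
#' scores plus a sentinel that calls nothing positive, so the curve runs
#' from (sensitivity 1, specificity 0) to (sensitivity 0, specificity 1).
#'
#' @param scores numeric scores, one per subject.
#' @param labels logical or 0/1 positive-class indicator.
#' @param direction `"higher"` if larger scores indicate the positive
#'   class, `"lower"` otherwise. The flag flips the comparison, not the
#'   data.
#' @return a `roc_curve` object: data frame with columns `threshold`,
#'   `sensitivity`, `specificity`, plus attributes `direction` and `auc`
#'   (trapezoidal area, which equals the tie-aware pairwise C-statistic).
#' @export
roc_curve <- function(scores, labels, direction = c("higher", "lower")) {
  direction <- match.arg(direction)
  labels <- as.logical(labels)
  if (!any(labels) || all(labels)) {
    stop("roc_curve domain error: both classes must be present", call. = FALSE)
  }
  if (anyNA(scores)) stop("roc_curve domain error: missing scores", call. = FALSE)
  dec <- direction == "lower"
  thr <- sort(unique(scores), decreasing = dec)
  thr <- c(thr, if (dec) -Inf else Inf)  # sentinel: nothing called positive
  calls <- lapply(thr, function(t) if (dec) scores <= t else scores >= t)
  sens <- vapply(calls, function(p) mean(p[labels]), numeric(1))
  spec <- vapply(calls, function(p) mean(!p[!labels]), numeric(1))
  curve <- data.frame(threshold = thr, sensitivity = sens, specificity = spec)
  fpr <- 1 - curve$specificity
  ord <- order(fpr, curve$sensitivity)
  auc <- sum(diff(fpr[ord]) * (utils::head(curve$sensitivity[ord], -1) +
                                 utils::tail(curve$sensitivity[ord], -1)) / 2)
  structure(curve, class = c("roc_curve", "data.frame"),
            direction = direction, auc = auc)
}

#' Select an operating threshold on a ROC curve
#'
#' The default criterion maximises Youden's J = sensitivity +
#' specificity - 1; ties are broken towards the smallest threshold value.
#' `criterion = "fixed"` imposes a given cutpoint (for published
#' thresholds) and reports the sensitivity/specificity attained there.
#'
#' @param curve a [roc_curve()].
#' @param criterion `"youden"` or `"fixed"`.
#' @param threshold cutpoint to impose when `criterion = "fixed"`.
#' @return list with `threshold`, `sensitivity`, `specificity`,
#'   `criterion`, `youden`.
#' @export
select_threshold <- function(curve, criterion = c("youden", "fixed"), threshold = NULL) {
  criterion <- match.arg(criterion)
  stopifnot(inherits(curve, "roc_curve"))
  if (criterion == "fixed") {
    if (is.null(threshold)) stop("fixed criterion requires a threshold", call. = FALSE)
    dec <- attr(curve, "direction") == "lower"
    ## The call set {score on the positive side of t, inclusive} coincides
    ## with the call set of the nearest grid cutpoint on the positive side,
    ## i.e. the smallest grid score >= t ("higher") or largest <= t ("lower");
    ## the sentinel row covers cutpoints beyond every observed score.
    idx <- if (dec) which(curve$threshold <= threshold) else which(curve$threshold >= threshold)
    row <- if (length(idx) == 0) {
      nrow(curve)
    } else if (dec) {
      idx[which.max(curve$threshold[idx])]
    } else {
      idx[which.min(curve$threshold[idx])]
    }
    return(list(threshold = threshold,
                sensitivity = curve$sensitivity[row],
                specificity = curve$specificity[row],
                criterion = "fixed",
                youden = curve$sensitivity[row] + curve$specificity[row] - 1))
  }
  j <- curve$sensitivity + curve$specificity - 1
  best <- which(j >= max(j) - 1e-12)
  pick <- best[which.min(curve$threshold[best])]
  list(threshold = curve$threshold[pick],
       sensitivity = curve$sensitivity[pick],
       specificity = curve$specificity[pick],
       criterion = "youden",
       youden = j[pick])
}
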