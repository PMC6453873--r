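#' Fit a binary logistic regression on a marker set
#'
#' Maximum-likelihood fit (iteratively reweighted least squares, via
#' [stats::glm()]) of `P(outcome) = logit^-1(intercept + sum_k beta_k
#' marker_k)`, with markers entering untransformed in their clinical
#' units. Complete or quasi-complete separation is surfaced as an error
#' naming the markers rather than silently returning diverged
#' coefficients.
#'
#' @param data data frame (typically a [cohort()]) holding the marker
#'   columns.
#' @param markers character vector of marker column names.
#' @param outcome logical (or 0/1) vector, one per row of `data`.
#' @return a `logistic_fit`: list with `markers`, `coefficients` (one per
#'   marker), `intercept`, `converged`, `n_iterations`, `deviance`.
#' @export
fit_logistic <- function(data, markers, outcome) {
  outcome <- as.logical(outcome)
  if (length(outcome) != nrow(data)) {
    stop("fit_logistic: outcome length must match rows of data", call. = FALSE)
  }
  if (sum(outcome) < 2 || sum(!outcome) < 2) {
    stop("fit_logistic: need at least 2 records per outcome class", call. = FALSE)
  }
  x <- as.matrix(as.data.frame(data)[, markers, drop = FALSE])
  if (anyNA(x)) {
    stop("fit_logistic: missing values in marker(s) ",
         paste(markers[colSums(is.na(x)) > 0], collapse = ", "), call. = FALSE)
  }
  if (qr(cbind(1, x))$rank < ncol(x) + 1) {
    stop("fit_logistic: singular design for markers ",
         paste(markers, collapse = ", "), call. = FALSE)
  }
  boundary_warn <- FALSE
  fit <- withCallingHandlers(
    stats::glm.fit(cbind("(Intercept)" = 1, x), as.numeric(outcome),
                   family = stats::binomial(),
                   control = stats::glm.control(epsilon = 1e-10, maxit = 100)),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)) ||
          grepl("algorithm did not converge", conditionMessage(w))) {
        boundary_warn <<- TRUE
        invokeRestart("muffleWarning")
      }
    }
  )
  eta <- fit$linear.predictors
  separated <- boundary_warn &&
    (min(eta[outcome]) >= max(eta[!outcome]) - 1e-6 ||
       max(eta[outcome]) <= min(eta[!outcome]) + 1e-6)
  if (separated || !fit$converged) {
    stop("fit_logistic separation error: outcome (quasi-)separated by marker(s) ",
         paste(markers, collapse = ", "), call. = FALSE)
  }
  coefs <- fit$coefficients
  if (anyNA(coefs)) {
    stop("fit_logistic: singular design for markers ",
         paste(markers, collapse = ", "), call. = FALSE)
  }
  structure(list(markers = markers,
                 coefficients = stats::setNames(coefs[-1], markers),
                 intercept = unname(coefs[1]),
                 converged = fit$converged && !boundary_warn,
                 n_iterations = fit$iter,
                 deviance = fit$deviance),
            class = "logistic_fit")
}

#' Linear predictor of a logistic fit
#' @param fit a `logistic_fit`.
#' @param data data frame carrying the fit's markers.
#' @return numeric vector `intercept + X %*% beta`.
#' @export
linear_predictor <- function(fit, data) {
  x <- as.matrix(as.data.frame(data)[, fit$markers, drop = FALSE])
  drop(fit$intercept + x %*% fit$coefficients)
}

#' Construct a composite biomarker index
#'
#' A composite index is a weighted sum `marker_1 + w_2 marker_2 + ...` in
#' raw clinical units, with the lead marker's weight fixed at 1, an
#' orientation (whether high or low values indicate the target group) and
#' an optional decision threshold. The published indices —
#' `C-peptide + 0.16 x BMI` (threshold 6.29, high = type 2 diabetes) and
#' `1,5-AG + 1.56 x hsCRP` (threshold 10.16, low = HNF1A MODY) — are
#' instances.
#'
#' @param markers ordered character vector of distinct marker names.
#' @param weights numeric weights, `weights[1]` must be 1.
#' @param direction `"higher_is_positive"` or `"lower_is_positive"`.
#' @param threshold optional decision threshold on the index scale.
#' @return a `composite_index` object.
#' @export
composite_index <- function(markers, weights = rep(1, length(markers)),
                            direction = c("higher_is_positive", "lower_is_positive"),
                            threshold = NULL) {
  direction <- match.arg(direction)
  if (anyDuplicated(markers)) stop("composite_index: markers must be distinct", call. = FALSE)
  if (length(weights) != length(markers) || abs(weights[1] - 1) > 1e-12) {
    stop("composite_index: weights must match markers with weights[1] == 1", call. = FALSE)
  }
  structure(list(markers = markers, weights = as.numeric(weights),
                 direction = direction, threshold = threshold),
            class = "composite_index")
}

#' @export
print.composite_index <- function(x, ...) {
  terms <- c(x$markers[1],
             if (length(x$markers) > 1)
               sprintf("%.4g x %s", x$weights[-1], x$markers[-1]))
  cat("<composite_index>", paste(terms, collapse = " + "), "\n")
  cat(sprintf("  direction: %s%s\n", x$direction,
              if (is.null(x$threshold)) "" else sprintf("; threshold %g", x$threshold)))
  invisible(x)
}

#' Reduce a logistic fit to a composite index
#'
#' Divides every coefficient by the lead marker's coefficient so the lead
#' weight is 1; the intercept is discarded (it is absorbed into the
#' decision threshold chosen later). The index orientation follows the
#' sign of the lead coefficient, so ranking patients by the index always
#' reproduces the ranking by the fitted linear predictor.
#'
#' @param fit a converged `logistic_fit`.
#' @return a [composite_index()].
#' @export
index_from_fit <- function(fit) {
  stopifnot(inherits(fit, "logistic_fit"))
  lead <- fit$coefficients[1]
  if (!is.finite(lead) || abs(lead) < 1e-12) {
    stop("index_from_fit: zero leading coefficient", call. = FALSE)
  }
  composite_index(fit$markers,
                  weights = unname(fit$coefficients / lead),
                  direction = if (lead > 0) "higher_is_positive" else "lower_is_positive")
}

#' Evaluate a composite index on patient records
#'
#' @param index a [composite_index()].
#' @param data a [cohort()] or data frame; every index marker must be
#'   present and non-missing in every row.
#' @return numeric index score per row, in the markers' stated units.
#' @export
evaluate_index <- function(index, data) {
  stopifnot(inherits(index, "composite_index"))
  data <- as.data.frame(data)
  missing_col <- setdiff(index$markers, names(data))
  if (length(missing_col) > 0) {
    stop("evaluate_index missing-data error: no column ",
         paste(missing_col, collapse = ", "), call. = FALSE)
  }
  for (mk in index$markers) {
    bad <- which(is.na(data[[mk]]))
    if (length(bad) > 0) {
      ids <- if ("id" %in% names(data)) data$id[bad] else as.character(bad)
      stop(sprintf("evaluate_index missing-data error: marker '%s' missing for record(s) %s",
                   mk, paste(utils::head(ids, 5), collapse = ", ")), call. = FALSE)
    }
  }
  x <- as.matrix(data[, index$markers, drop = FALSE])
  unname(drop(x %*% index$weights))
}
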