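#' @keywords internal
"_PACKAGE"

## Canonical group labels (display order follows the clinical tables;
## tie-break order used by the tree builder is mody_group_priority()).
mody_groups <- function() c("HNF1A", "GCK", "T1D", "T2D")

mody_group_priority <- function() c("T1D", "T2D", "HNF1A", "GCK")

cohort_columns <- function() {
  c("id", "group", "sex", "age", "diabetes_duration", "age_at_diagnosis",
    "bmi", "creatinine", "hba1c", "fasting_glucose", "c_peptide",
    "hscrp", "ag15", "treatment")
}

cohort_numeric_columns <- function() {
  c("age", "diabetes_duration", "age_at_diagnosis", "bmi", "creatinine",
    "hba1c", "fasting_glucose", "c_peptide", "hscrp", "ag15")
}

#' Construct a validated patient cohort
#'
#' A cohort is a data frame with one row per patient, fixed lowercase
#' column names, and fixed units: age and durations in years, BMI in
#' kg/m^2, creatinine in umol/l, HbA1c in % (NGSP), fasting glucose in
#' mmol/l, fasting serum C-peptide in ng/ml, hsCRP in mg/l and
#' 1,5-anhydroglucitol (`ag15`) in ug/ml. No unit conversion is performed.
#'
#' Hard invariants (unique ids; strictly positive numeric values where
#' present; recognised group/sex/treatment codes) reject the offending rows
#' with row-indexed diagnostics. Plausibility bounds (BMI in (10, 80),
#' HbA1c in (3, 20)) only raise warnings: implausible values are retained.
#'
#' @param data data frame carrying the columns of [cohort_columns()].
#' @param provenance free-text origin of the records (file path, or a
#'   simulation seed/config digest).
#' @return A `cohort` object: a data frame of class `c("cohort",
#'   "data.frame")` with a `provenance` attribute.
#' @export
cohort <- function(data, provenance = "constructed") {
  data <- as.data.frame(data, stringsAsFactors = FALSE)
  missing_cols <- setdiff(cohort_columns(), names(data))
  if (length(missing_cols) > 0) {
    stop("cohort format error: missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  data <- data[, cohort_columns()]
  data$id <- as.character(data$id)
  data$group <- as.character(data$group)
  data$sex <- as.character(data$sex)
  data$treatment <- as.character(data$treatment)
  for (col in cohort_numeric_columns()) {
    if (!is.numeric(data[[col]])) {
      suppressWarnings(num <- as.numeric(data[[col]]))
      bad <- which(!is.na(data[[col]]) & nzchar(trimws(data[[col]])) & is.na(num))
      if (length(bad) > 0) {
        stop(sprintf("cohort row error: unparseable numeric in column '%s', row(s) %s",
                     col, paste(bad, collapse = ", ")), call. = FALSE)
      }
      data[[col]] <- num
    }
  }
  data$group[!is.na(data$group) & !nzchar(data$group)] <- NA_character_
  data$treatment[!is.na(data$treatment) & !nzchar(data$treatment)] <- NA_character_
  data$sex[!is.na(data$sex) & !nzchar(data$sex)] <- NA_character_

  reject <- character(0)
  bad_rows <- logical(nrow(data))
  flag <- function(rows, msg) {
    rows <- rows[!bad_rows[rows]]
    if (length(rows) > 0) {
      bad_rows[rows] <<- TRUE
      reject <<- c(reject, sprintf("row %d: %s", rows, msg))
    }
  }
  bad_group <- which(!is.na(data$group) & !data$group %in% mody_groups())
  flag(bad_group, "unknown group label")
  bad_sex <- which(!is.na(data$sex) & !data$sex %in% c("F", "M"))
  flag(bad_sex, "sex must be F or M")
  bad_trt <- which(!is.na(data$treatment) &
                     !data$treatment %in% c("insulin", "non_insulin", "diet"))
  flag(bad_trt, "unknown treatment code")
  for (col in cohort_numeric_columns()) {
    flag(which(!is.na(data[[col]]) & data[[col]] <= 0),
         sprintf("non-positive %s", col))
  }
  dup <- which(duplicated(data$id))
  flag(dup, "duplicate id")
  if (length(reject) > 0) {
    warning("cohort validation rejected ", sum(bad_rows), " row(s):\n  ",
            paste(reject, collapse = "\n  "), call. = FALSE)
    data <- data[!bad_rows, , drop = FALSE]
  }

  warn_bounds <- function(col, lo, hi) {
    n <- sum(!is.na(data[[col]]) & (data[[col]] <= lo | data[[col]] >= hi))
    if (n > 0) {
      warning(sprintf("cohort plausibility: %d value(s) of %s outside (%g, %g)",
                      n, col, lo, hi), call. = FALSE)
    }
  }
  warn_bounds("bmi", 10, 80)
  warn_bounds("hba1c", 3, 20)

  rownames(data) <- NULL
  structure(data, class = c("cohort", "data.frame"), provenance = provenance)
}

#' @export
print.cohort <- function(x, ...) {
  grp <- table(factor(x$group, levels = mody_groups()), useNA = "ifany")
  cat(sprintf("<cohort> %d patients (%s)\n", nrow(x),
              paste(sprintf("%s: %d", names(grp), as.integer(grp)), collapse = ", ")))
  cat("provenance:", attr(x, "provenance"), "\n")
  invisible(x)
}

#' Read a cohort table from delimited text
#'
#' Reads a comma-separated table with a header row naming every column of
#' [cohort_columns()] (lowercase snake case, fixed units, decimal point).
#' Missing values are empty cells; the group label may be empty for
#' records that are only to be classified.
#'
#' @param path path to an existing CSV file.
#' @return A validated [cohort()], with the file path as provenance.
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) {
    stop("cohort I/O error: file not found: ", path, call. = FALSE)
  }
  raw <- utils::read.csv(path, colClasses = "character",
                         check.names = FALSE, na.strings = NULL)
  cohort(raw, provenance = path)
}

#' Write a cohort table to delimited text
#'
#' Columns are written in the fixed order of [cohort_columns()]; numeric
#' values are rendered with 17 significant digits so that
#' `read_cohort(write_cohort(x))` round-trips every double exactly.
#'
#' @param x a non-empty [cohort()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(x, path) {
  stopifnot(inherits(x, "cohort"))
  if (nrow(x) == 0) stop("cannot write an empty cohort", call. = FALSE)
  out <- as.data.frame(x)[, cohort_columns()]
  for (col in cohort_numeric_columns()) {
    v <- out[[col]]
    s <- vapply(v, function(z) {
      if (is.na(z)) "" else formatC(z, digits = 17, format = "g")
    }, character(1))
    out[[col]] <- s
  }
  for (col in c("group", "sex", "treatment")) {
    out[[col]][is.na(out[[col]])] <- ""
  }
  ok <- tryCatch({
    utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
    TRUE
  }, error = function(e) FALSE)
  if (!ok) stop("cohort I/O error: cannot write to ", path, call. = FALSE)
  invisible(path)
}
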