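#' Declare a feature of a cohort schema
#'
#' A cohort schema is a list of feature specifications. Each feature is
#' continuous, dichotomous (exactly two levels) or polytomous (three or more
#' levels). Categorical levels are ordered; the order fixes one-hot column
#' order downstream and breaks mode-imputation ties.
#'
#' @param name Feature name (unique within a schema).
#' @param kind One of `"continuous"`, `"dichotomous"`, `"polytomous"`.
#' @param levels Character vector of category labels; required for
#'   categorical kinds, disallowed for continuous.
#' @param units Free-text units annotation.
#' @return An object of class `feature_spec`.
#' @export
feature_spec <- function(name, kind = c("continuous", "dichotomous", "polytomous"),
                         levels = NULL, units = "") {
  kind <- match.arg(kind)
  stopifnot(is.character(name), length(name) == 1, nzchar(name))
  if (kind == "continuous") {
    if (!is.null(levels)) stop("continuous feature '", name, "' must not have levels")
  } else {
    if (is.null(levels)) stop("categorical feature '", name, "' needs levels")
    levels <- as.character(levels)
    if (anyDuplicated(levels)) stop("duplicate levels in feature '", name, "'")
    if (kind == "dichotomous" && length(levels) != 2)
      stop("dichotomous feature '", name, "' must have exactly 2 levels")
    if (kind == "polytomous" && length(levels) < 3)
      stop("polytomous feature '", name, "' must have >= 3 levels")
  }
  structure(list(name = name, kind = kind, levels = levels, units = units),
            class = "feature_spec")
}

#' Assemble a cohort schema
#'
#' @param ... `feature_spec` objects (or a single list of them).
#' @return A named list of `feature_spec`, class `cohort_schema`.
#' @export
cohort_schema <- function(...) {
  specs <- list(...)
  if (length(specs) == 1 && !inherits(specs[[1]], "feature_spec")) specs <- specs[[1]]
  stopifnot(all(vapply(specs, inherits, logical(1), "feature_spec")))
  nm <- vapply(specs, `[[`, character(1), "name")
  if (anyDuplicated(nm)) stop("duplicate feature names in schema")
  names(specs) <- nm
  structure(specs, class = "cohort_schema")
}

schema_names <- function(schema) vapply(schema, `[[`, character(1), "name")

#' Construct a cohort table
#'
#' The central data container: one row per subject, with a subject identifier,
#' a recruitment-site identifier, a binary conversion outcome (1 = converter,
#' 0 = non-converter) and one column per schema feature. Missing values are
#' `NA`. Site and subject ids are opaque strings.
#'
#' @param subject_id,site_id Character vectors.
#' @param outcome Vector coercible to 0/1; accepts 0/1, "NC"/"cAD".
#' @param features data.frame of feature columns matching `schema`.
#' @param schema A `cohort_schema`.
#' @return A data.frame of class `cohort_table` with the schema attached as
#'   attribute `"schema"`.
#' @export
cohort_table <- function(subject_id, site_id, outcome, features, schema) {
  subject_id <- as.character(subject_id)
  site_id <- as.character(site_id)
  if (anyDuplicated(subject_id)) stop("duplicate subject id")
  outcome <- normalize_outcome(outcome)
  if (anyNA(outcome)) stop("outcome contains missing or unrecognized values")
  n <- length(subject_id)
  if (length(site_id) != n || length(outcome) != n || nrow(features) != n)
    stop("subject_id, site_id, outcome and features must have equal length")
  nm <- schema_names(schema)
  missing_cols <- setdiff(nm, names(features))
  if (length(missing_cols))
    stop("features missing schema column(s): ", paste(missing_cols, collapse = ", "))
  features <- features[nm]
  for (f in schema) {
    v <- features[[f$name]]
    if (f$kind == "continuous") {
      if (!is.numeric(v)) {
        v <- suppressWarnings(as.numeric(as.character(v)))
        if (any(is.na(v) & !is.na(features[[f$name]]) & features[[f$name]] != ""))
          stop("non-numeric value in continuous feature '", f$name, "'")
      }
    } else {
      v <- as.character(v)
      v[!is.na(v) & v == ""] <- NA_character_
      bad <- !is.na(v) & !(v %in% f$levels)
      if (any(bad))
        stop("value(s) outside declared levels in feature '", f$name, "': ",
             paste(unique(v[bad]), collapse = ", "))
    }
    features[[f$name]] <- v
  }
  out <- data.frame(subject_id = subject_id, site_id = site_id,
                    outcome = outcome, features,
                    stringsAsFactors = FALSE, check.names = FALSE)
  structure(out, schema = schema, class = c("cohort_table", "data.frame"))
}

normalize_outcome <- function(x) {
  x <- as.character(x)
  map <- c("0" = 0L, "1" = 1L, "NC" = 0L, "cAD" = 1L)
  out <- unname(map[x])
  if (any(is.na(out) & !is.na(x)))
    stop("outcome values must be 0/1 or NC/cAD; got: ",
         paste(unique(x[is.na(out) & !is.na(x)]), collapse = ", "))
  out
}

#' @export
print.cohort_table <- function(x, ...) {
  sch <- attr(x, "schema")
  cat(sprintf("Cohort table: %d subjects, %d sites, %d features\n",
              nrow(x), length(unique(x$site_id)), length(sch)))
  cat(sprintf("Converters: %d (%.2f%%)\n", sum(x$outcome),
              100 * mean(x$outcome)))
  invisible(x)
}

#' Read a cohort table from CSV
#'
#' Expects columns `subject_id, site_id, outcome` followed by one column per
#' schema feature. Missing cells are empty strings or `na` sentinels.
#'
#' @param path CSV file path.
#' @param schema A `cohort_schema`.
#' @param na Missing-value sentinel(s) in the file (default: empty string).
#' @return A `cohort_table`; row order preserved.
#' @export
read_cohort <- function(path, schema, na = c("", "NA")) {
  df <- utils::read.csv(path, colClasses = "character", check.names = FALSE,
                        na.strings = na)
  for (col in c("subject_id", "site_id", "outcome"))
    if (!col %in% names(df)) stop("missing mandatory column '", col, "'")
  nm <- schema_names(schema)
  absent <- setdiff(nm, names(df))
  if (length(absent))
    stop("missing feature column(s): ", paste(absent, collapse = ", "))
  cohort_table(df$subject_id, df$site_id, df$outcome, df[nm], schema)
}

#' Write a cohort table to CSV
#'
#' Inverse of [read_cohort()]: `read_cohort(write_cohort(x, p), schema)` is the
#' identity on values, ordering and missingness markers.
#'
#' @param table A `cohort_table`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(table, path) {
  utils::write.csv(as.data.frame(table), path, row.names = FALSE, na = "")
  invisible(path)
}

#' Per-feature missingness summary
#'
#' @param table A `cohort_table`.
#' @return data.frame with `feature`, `n_missing`, `frac_missing`
#'   (exactly `n_missing / n_subjects`).
#' @export
summarize_missing <- function(table) {
  sch <- attr(table, "schema")
  nm <- schema_names(sch)
  n <- nrow(table)
  cnt <- vapply(nm, function(f) sum(is.na(table[[f]])), integer(1))
  data.frame(feature = nm, n_missing = unname(cnt),
             frac_missing = unname(cnt) / n, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Converter prevalence of a cohort
#'
#' @param table A `cohort_table` (non-empty).
#' @return Fraction of subjects with outcome 1.
#' @export
class_prevalence <- function(table) {
  if (nrow(table) == 0) stop("empty cohort table")
  mean(table$outcome)
}

#' Subset a cohort table by row index, keeping the schema
#' @param table A `cohort_table`.
#' @param idx Row index vector.
#' @return A `cohort_table`.
#' @export
cohort_subset <- function(table, idx) {
  out <- as.data.frame(table)[idx, , drop = FALSE]
  rownames(out) <- NULL
  structure(out, schema = attr(table, "schema"),
            class = c("cohort_table", "data.frame"))
}
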