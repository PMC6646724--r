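#' Drop features with excessive missingness
#'
#' Features whose missing fraction is strictly greater than `cutoff` are
#' removed from the table and its schema (a feature at exactly the cutoff is
#' retained).
#'
#' @param table A `cohort_table`.
#' @param cutoff Missing-fraction cutoff (default 0.20).
#' @return List with `table` (features removed) and `dropped` (data.frame of
#'   feature, frac_missing).
#' @export
drop_high_missing <- function(table, cutoff = 0.20) {
  ms <- summarize_missing(table)
  drop <- ms$feature[ms$frac_missing > cutoff]
  if (length(drop) == nrow(ms)) stop("all features exceed the missingness cutoff")
  sch <- attr(table, "schema")
  keep <- setdiff(schema_names(sch), drop)
  df <- as.data.frame(table)[c("subject_id", "site_id", "outcome", keep)]
  out <- structure(df, schema = cohort_schema(sch[keep]),
                   class = c("cohort_table", "data.frame"))
  list(table = out,
       dropped = ms[ms$feature %in% drop, c("feature", "frac_missing")])
}

mode_of <- function(x, levels) {
  tab <- table(factor(x[!is.na(x)], levels = levels))
  levels[which.max(tab)]  # ties broken by first level in schema order
}

#' Fit the train-only feature transformation
#'
#' Fits, on a training cohort only, the full transformation the test data
#' will receive: (1) drop features missing more than `missing_cutoff`;
#' (2) impute remaining missing values (median for continuous, mode for
#' categorical); (3) compute standardization parameters for continuous
#' features on the imputed data; (4) build one-hot maps for categorical
#' features (all levels kept, no reference level dropped); (5) group
#' standardized continuous features whose pairwise training |r| meets
#' `r_threshold` (connected components of the correlation graph) and replace
#' each group by its correlation-matrix principal components with
#' eigenvalue >= `eig_threshold` (Kaiser rule), sign fixed so the first
#' member's loading is positive.
#'
#' @param table Training `cohort_table`.
#' @param missing_cutoff Missingness exclusion cutoff (default 0.20).
#' @param r_threshold Absolute pairwise correlation defining a group
#'   (default 0.75).
#' @param eig_threshold Minimum eigenvalue of a retained component
#'   (default 1.0).
#' @param fitted_on Identifier of the training subset (audit metadata).
#' @return Object of class `preprocess_model`.
#' @export
fit_preprocess <- function(table, missing_cutoff = 0.20, r_threshold = 0.75,
                           eig_threshold = 1.0, fitted_on = NA_character_) {
  dropped <- drop_high_missing(table, missing_cutoff)
  table <- dropped$table
  sch <- attr(table, "schema")
  cont <- schema_names(sch)[vapply(sch, function(f) f$kind == "continuous", logical(1))]
  catf <- setdiff(schema_names(sch), cont)

  impute <- list()
  for (nm in cont) impute[[nm]] <- stats::median(table[[nm]], na.rm = TRUE)
  for (nm in catf) impute[[nm]] <- mode_of(table[[nm]], sch[[nm]]$levels)

  std <- list()
  Z <- matrix(NA_real_, nrow(table), length(cont), dimnames = list(NULL, cont))
  for (nm in cont) {
    v <- table[[nm]]
    v[is.na(v)] <- impute[[nm]]
    m <- mean(v)
    s <- stats::sd(v)
    if (!is.finite(s) || s == 0)
      stop("zero-variance continuous feature '", nm, "' in training data")
    std[[nm]] <- c(mean = m, sd = s)
    Z[, nm] <- (v - m) / s
  }

  ## correlation groups: connected components of |r| >= threshold
  groups <- list()
  if (length(cont) >= 2) {
    R <- stats::cor(Z)
    adj <- abs(R) >= r_threshold
    comp <- rep(NA_integer_, length(cont))
    cid <- 0L
    for (i in seq_along(cont)) {
      if (!is.na(comp[i])) next
      cid <- cid + 1L
      queue <- i
      while (length(queue)) {
        v <- queue[1]; queue <- queue[-1]
        if (!is.na(comp[v])) next
        comp[v] <- cid
        queue <- c(queue, which(adj[v, ] & is.na(comp)))
      }
    }
    for (g in unique(comp)) {
      members <- cont[comp == g]
      if (length(members) < 2) next
      eg <- eigen(stats::cor(Z[, members, drop = FALSE]), symmetric = TRUE)
      keep <- which(eg$values >= eig_threshold)
      load <- eg$vectors[, keep, drop = FALSE]
      for (j in seq_len(ncol(load)))
        if (load[1, j] < 0) load[, j] <- -load[, j]
      rownames(load) <- members
      groups[[length(groups) + 1]] <- list(
        members = members, loadings = load, eigenvalues = eg$values,
        components = paste0(group_label(members), "_PC", seq_along(keep))
      )
    }
  }

  onehot <- list()
  for (nm in catf) {
    f <- sch[[nm]]
    if (f$kind == "dichotomous") {
      onehot[[nm]] <- list(kind = "dichotomous", levels = f$levels, columns = nm)
    } else {
      onehot[[nm]] <- list(kind = "polytomous", levels = f$levels,
                           columns = paste(nm, f$levels, sep = "_"))
    }
  }

  structure(list(schema = sch, dropped_features = dropped$dropped,
                 impute_values = impute, standardize_params = std,
                 onehot_map = onehot, correlation_groups = groups,
                 r_threshold = r_threshold, eig_threshold = eig_threshold,
                 missing_cutoff = missing_cutoff, fitted_on = fitted_on),
            class = "preprocess_model")
}

## Group label: longest common prefix of member names (trimmed of trailing
## separators), falling back to the first member.
group_label <- function(members) {
  pre <- members[1]
  for (m in members[-1]) {
    while (nchar(pre) && substr(m, 1, nchar(pre)) != pre)
      pre <- substr(pre, 1, nchar(pre) - 1)
  }
  pre <- sub("[_.-]+$", "", pre)
  if (nchar(pre) < 2) pre <- members[1]
  pre
}

#' Apply a fitted preprocessing model
#'
#' Transforms any cohort with the statistics learned on the training subset:
#' training imputation values, training standardization parameters, the
#' training one-hot maps and the training component loadings. Unseen
#' categorical levels map to all-zero indicators with a warning.
#'
#' @param object A `preprocess_model`.
#' @param table A `cohort_table` with a schema compatible with the model's.
#' @param ... Unused.
#' @return Numeric design matrix; attribute `"column_info"` is a data.frame
#'   with `name` and `type` (`"continuous"` or `"indicator"`) per column.
#' @export
predict.preprocess_model <- function(object, table, ...) {
  sch <- object$schema
  n <- nrow(table)
  cont <- names(object$standardize_params)
  Z <- matrix(NA_real_, n, length(cont), dimnames = list(NULL, cont))
  for (nm in cont) {
    if (!nm %in% names(table)) stop("column '", nm, "' absent from table")
    v <- table[[nm]]
    v[is.na(v)] <- object$impute_values[[nm]]
    p <- object$standardize_params[[nm]]
    Z[, nm] <- (v - p[["mean"]]) / p[["sd"]]
  }
  grouped <- unlist(lapply(object$correlation_groups, `[[`, "members"))
  cols <- list()
  types <- character(0)
  for (nm in setdiff(cont, grouped)) {
    cols[[nm]] <- Z[, nm]
    types <- c(types, "continuous")
  }
  for (g in object$correlation_groups) {
    S <- Z[, g$members, drop = FALSE] %*% g$loadings
    for (j in seq_along(g$components)) {
      cols[[g$components[j]]] <- S[, j]
      types <- c(types, "continuous")
    }
  }
  for (nm in names(object$onehot_map)) {
    oh <- object$onehot_map[[nm]]
    v <- as.character(table[[nm]])
    v[is.na(v)] <- object$impute_values[[nm]]
    unseen <- !(v %in% oh$levels)
    if (any(unseen)) {
      warning("unseen level(s) in '", nm, "': ",
              paste(unique(v[unseen]), collapse = ", "),
              "; encoded as all-zero indicators")
    }
    if (oh$kind == "dichotomous") {
      cols[[oh$columns]] <- as.numeric(v == oh$levels[2])
      types <- c(types, "indicator")
    } else {
      for (j in seq_along(oh$levels)) {
        cols[[oh$columns[j]]] <- as.numeric(v == oh$levels[j])
        types <- c(types, "indicator")
      }
    }
  }
  X <- do.call(cbind, cols)
  colnames(X) <- names(cols)
  attr(X, "column_info") <- data.frame(name = names(cols), type = types,
                                       stringsAsFactors = FALSE)
  X
}

#' @export
print.preprocess_model <- function(x, ...) {
  cat(sprintf("Preprocessing model: %d features in, %d dropped, %d groups\n",
              length(x$schema), nrow(x$dropped_features),
              length(x$correlation_groups)))
  for (g in x$correlation_groups)
    cat(" group {", paste(g$members, collapse = ", "), "} -> ",
        paste(g$components, collapse = ", "), "\n", sep = "")
  invisible(x)
}
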