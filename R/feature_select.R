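#' Univariate filter feature selection
#'
#' Keeps continuous-derived columns with two-sample t-test p < `alpha`
#' (pooled-variance Student's t by default; Welch via `var_equal = FALSE`)
#' and indicator columns with two-sided Fisher exact test p < `alpha`
#' (2x2 indicator x outcome table). Constant columns are excluded with a
#' warning (the tests are undefined for them).
#'
#' @param X Design matrix from [predict.preprocess_model()] (carries
#'   `"column_info"`), or any numeric matrix if `col_types` is given.
#' @param y 0/1 outcome vector.
#' @param alpha Significance level (default 0.05).
#' @param col_types Optional character vector (`"continuous"`/`"indicator"`)
#'   per column; defaults to the matrix's `column_info`.
#' @param var_equal Pooled-variance t-test if `TRUE` (default).
#' @return Character vector of selected column names, with attribute
#'   `"p_values"`.
#' @export
filter_univariate <- function(X, y, alpha = 0.05, col_types = NULL,
                              var_equal = TRUE) {
  col_types <- col_types %||% attr(X, "column_info")$type
  stopifnot(length(col_types) == ncol(X))
  p <- rep(NA_real_, ncol(X))
  for (j in seq_len(ncol(X))) {
    v <- X[, j]
    if (stats::var(v) == 0) {
      warning("constant column '", colnames(X)[j], "' excluded from filter")
      next
    }
    p[j] <- if (col_types[j] == "continuous") {
      ## a column constant within both classes has an undefined t statistic;
      ## it separates the classes perfectly, so keep it (p = 0)
      tryCatch(stats::t.test(v[y == 1], v[y == 0],
                             var.equal = var_equal)$p.value,
               error = function(e) 0)
    } else {
      stats::fisher.test(table(factor(v > 0.5, levels = c(FALSE, TRUE)),
                               factor(y, levels = c(0, 1))))$p.value
    }
  }
  keep <- !is.na(p) & p < alpha
  structure(colnames(X)[keep], p_values = stats::setNames(p, colnames(X)))
}

## Importance ranking used inside RFE.
## logistic: |coefficient| of a ridge-penalized logistic fit on the (already
## standardized) design; random_forest: impurity importance of a 500-tree
## forest (tree count tunable for reduced profiles).
rfe_importance <- function(X, y, base, ntree = 500) {
  if (base == "logistic") {
    if (ncol(X) == 1) return(stats::setNames(1, colnames(X)))
    fit <- glmnet::glmnet(X, y, family = "binomial", alpha = 0,
                          lambda = 1 / nrow(X), standardize = FALSE)
    abs(stats::setNames(as.numeric(fit$beta), rownames(fit$beta)))
  } else {
    rf <- randomForest::randomForest(X, factor(y, levels = c(0, 1)),
                                     ntree = ntree)
    imp <- randomForest::importance(rf)[, 1]
    stats::setNames(as.numeric(imp), colnames(X))
  }
}

rfe_cv_score <- function(X, y, base, folds, ntree) {
  fold <- stratified_folds(y, folds)
  aucs <- numeric(folds)
  for (f in seq_len(folds)) {
    tr <- fold != f
    if (length(unique(y[!tr])) < 2 || length(unique(y[tr])) < 2)
      stop("degenerate fold without both classes")
    s <- if (base == "logistic") {
      d <- data.frame(y = y[tr], X[tr, , drop = FALSE], check.names = FALSE)
      m <- suppressWarnings(stats::glm(y ~ ., data = d, family = stats::binomial()))
      nd <- data.frame(X[!tr, , drop = FALSE], check.names = FALSE)
      suppressWarnings(stats::predict(m, nd, type = "response"))
    } else {
      rf <- randomForest::randomForest(X[tr, , drop = FALSE],
                                       factor(y[tr], levels = c(0, 1)),
                                       ntree = ntree)
      stats::predict(rf, X[!tr, , drop = FALSE], type = "prob")[, "1"]
    }
    aucs[f] <- auroc(s, y[!tr])
  }
  mean(aucs)
}

#' Cross-validated recursive feature elimination
#'
#' Wrapper selection: starting from all columns, the least important column
#' (ridge-logistic |coefficient| or random-forest impurity importance) is
#' removed one at a time; every visited subset size is scored by stratified
#' k-fold AUROC of the base learner, and the size with maximal mean CV AUROC
#' is returned (ties favour the smaller set). Degenerate folds are re-drawn
#' with a fresh seed up to 5 times.
#'
#' @param X Design matrix (standardized continuous columns).
#' @param y 0/1 outcome.
#' @param base `"logistic"` or `"random_forest"`.
#' @param folds Inner CV folds (default 10, single repetition).
#' @param seed Integer seed.
#' @param ntree Trees for the forest wrapper (default 500).
#' @return Character vector of selected column names; attribute `"path"`
#'   records the visited sizes and their CV scores.
#' @export
rfe_cv <- function(X, y, base = c("logistic", "random_forest"), folds = 10,
                   seed = 1, ntree = 500) {
  base <- match.arg(base)
  stopifnot(ncol(X) >= 2)
  with_seed(derive_seed(seed, "select"), {
    current <- colnames(X)
    sizes <- integer(0)
    scores <- numeric(0)
    sets <- list()
    while (length(current) >= 1) {
      Xc <- X[, current, drop = FALSE]
      sc <- NULL
      for (attempt in 1:5) {
        sc <- tryCatch(rfe_cv_score(Xc, y, base, folds, ntree),
                       error = function(e) NULL)
        if (!is.null(sc)) break
      }
      if (is.null(sc)) stop("could not form folds with both classes; use fewer folds")
      sizes <- c(sizes, length(current))
      scores <- c(scores, sc)
      sets[[length(sets) + 1]] <- current
      if (length(current) == 1) break
      imp <- rfe_importance(Xc, y, base, ntree)
      current <- setdiff(current, names(which.min(imp)))
    }
    ## maximal score; ties -> smaller set (later entries have fewer columns)
    best <- which(scores >= max(scores) - 1e-12)
    pick <- best[which.max(best)]
    structure(sets[[pick]],
              path = data.frame(size = sizes, cv_auroc = scores))
  })
}

#' Build the four feature sets for one training subset
#'
#' Set 1 is all design-matrix columns; set 2 the univariate filter; sets 3
#' and 4 cross-validated recursive elimination with logistic regression and
#' random forest respectively.
#'
#' @param X Training design matrix (with `column_info`).
#' @param y 0/1 outcome.
#' @param alpha Filter significance level.
#' @param folds Wrapper CV folds.
#' @param seed Integer seed.
#' @param ntree Wrapper forest size.
#' @return Named list of four character vectors
#'   (`set1_all`, `set2_filter`, `set3_rfe_lr`, `set4_rfe_rf`), class
#'   `feature_sets`.
#' @export
build_feature_sets <- function(X, y, alpha = 0.05, folds = 10, seed = 1,
                               ntree = 500) {
  s2 <- filter_univariate(X, y, alpha = alpha)
  if (!length(s2)) s2 <- colnames(X)  # degenerate cohorts: fall back to all
  structure(list(
    set1_all = colnames(X),
    set2_filter = as.character(s2),
    set3_rfe_lr = as.character(rfe_cv(X, y, "logistic", folds, seed, ntree)),
    set4_rfe_rf = as.character(rfe_cv(X, y, "random_forest", folds, seed + 1, ntree))
  ), class = "feature_sets")
}
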