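#' Repeated stratified cross-validation of one configuration
#'
#' Runs `repeats` independent stratified `folds`-fold cross-validations of a
#' technique at a fixed hyper-parameter configuration. Each repeat draws a
#' fresh stratified fold assignment; out-of-fold continuous scores in [0, 1]
#' are recorded per case, AUROC is computed per held-out fold, and all
#' `repeats * folds` estimates are returned alongside their mean. Each
#' subject receives exactly one out-of-fold score per repeat; the per-case
#' cross-validated score is their arithmetic mean.
#'
#' @param technique A descriptor from [technique_registry()].
#' @param config Named list of hyper-parameter values.
#' @param X Design matrix.
#' @param y 0/1 outcome.
#' @param repeats,folds CV geometry (defaults 10 and 10).
#' @param seed Integer seed.
#' @return List of class `cv_result`: `per_estimate_auroc` (length
#'   `repeats * folds`), `mean_auroc`, `per_case_cv_score` (length `n`),
#'   `technique`, `config`.
#' @export
cv_evaluate <- function(technique, config, X, y, repeats = 10, folds = 10,
                        seed = 1) {
  stopifnot(length(unique(y)) == 2, nrow(X) >= folds)
  with_seed(derive_seed(seed, "cv"), {
    n <- nrow(X)
    est <- numeric(0)
    case_scores <- matrix(NA_real_, n, repeats)
    for (r in seq_len(repeats)) {
      fold <- stratified_folds(y, folds)
      if (any(tabulate(fold[y == 1], folds) == 0) ||
          any(tabulate(fold[y == 0], folds) == 0))
        stop("a fold lacks one class even after stratification; use fewer folds")
      info <- attr(X, "column_info")
      for (f in seq_len(folds)) {
        tr <- fold != f
        Xtr <- X[tr, , drop = FALSE]
        Xte <- X[!tr, , drop = FALSE]
        attr(Xtr, "column_info") <- info
        attr(Xte, "column_info") <- info
        model <- technique$fit(Xtr, y[tr], config)
        s <- as.numeric(technique$predict(model, Xte))
        s <- pmin(pmax(s, 0), 1)
        case_scores[!tr, r] <- s
        est <- c(est, auroc(s, y[!tr]))
      }
    }
    structure(list(technique = technique$name, config = config,
                   per_estimate_auroc = est, mean_auroc = mean(est),
                   per_case_cv_score = rowMeans(case_scores)),
              class = "cv_result")
  })
}

## ---- Gaussian-process surrogate for Bayesian hyper-parameter search ------
## Zero-mean GP on the unit hypercube with a squared-exponential kernel
## (fixed length-scale 0.2, unit signal variance, jittered nugget) over
## standardized objective values; proposals maximize expected improvement
## over a random candidate set. Falls back to a random draw if the Cholesky
## factorization fails.
gp_propose <- function(U, yv, n_cand = 500, lengthscale = 0.2, noise = 1e-4) {
  d <- ncol(U)
  mu_y <- mean(yv); sd_y <- stats::sd(yv)
  if (!is.finite(sd_y) || sd_y == 0) sd_y <- 1
  z <- (yv - mu_y) / sd_y
  sq <- function(A, B) {
    outer(rowSums(A^2), rowSums(B^2), `+`) - 2 * tcrossprod(A, B)
  }
  K <- exp(-0.5 * pmax(sq(U, U), 0) / lengthscale^2) + diag(noise, nrow(U))
  ch <- tryCatch(chol(K), error = function(e) NULL)
  if (is.null(ch)) return(NULL)
  alpha <- backsolve(ch, forwardsolve(t(ch), z))
  C <- matrix(stats::runif(n_cand * d), n_cand, d)
  Ks <- exp(-0.5 * pmax(sq(C, U), 0) / lengthscale^2)
  mu <- as.numeric(Ks %*% alpha)
  v <- forwardsolve(t(ch), t(Ks))
  s2 <- pmax(1 + noise - colSums(v^2), 1e-12)
  s <- sqrt(s2)
  best <- max(z)
  imp <- mu - best
  zz <- imp / s
  ei <- imp * stats::pnorm(zz) + s * stats::dnorm(zz)
  C[which.max(ei), ]
}

#' Optimize an objective over a hyper-parameter space
#'
#' `n_random` uniform draws from the space followed by `n_bayes` sequential
#' Gaussian-process proposals (expected-improvement acquisition) fitted to
#' all previous (configuration, value) pairs. Deterministic given `seed`.
#' An empty space is evaluated once.
#'
#' @param space Named list of dimension descriptors (see
#'   [technique_registry()]).
#' @param objective Function(config) -> numeric value to maximize.
#' @param n_random,n_bayes Evaluation budgets (defaults 50 and 50).
#' @param seed Integer seed.
#' @return List: `best_config`, `best_value`, `history` (data.frame of
#'   evaluation index, value), `configs` (all evaluated configurations).
#' @export
optimize_config <- function(space, objective, n_random = 50, n_bayes = 50,
                            seed = 1) {
  if (!length(space)) {
    val <- objective(list())
    return(list(best_config = list(), best_value = val,
                history = data.frame(eval = 1L, value = val),
                configs = list(list())))
  }
  with_seed(derive_seed(seed, "search"), {
    d <- length(space)
    U <- matrix(NA_real_, 0, d)
    vals <- numeric(0)
    configs <- list()
    evaluate <- function(u) {
      cfg <- config_from_unit(space, u)
      U <<- rbind(U, u)
      configs[[length(configs) + 1]] <<- cfg
      vals <<- c(vals, objective(cfg))
    }
    for (i in seq_len(n_random)) evaluate(stats::runif(d))
    for (i in seq_len(n_bayes)) {
      u <- gp_propose(U, vals)
      if (is.null(u)) u <- stats::runif(d)
      evaluate(u)
    }
    best <- which.max(vals)
    list(best_config = configs[[best]], best_value = vals[best],
         history = data.frame(eval = seq_along(vals), value = vals),
         configs = configs)
  })
}

#' Hyper-parameter search for one technique
#'
#' Cross-validated AUROC (mean of the `repeats * folds` estimates) is the
#' objective maximized by [optimize_config()]. Returns the best
#' configuration's full `cv_result`.
#'
#' @inheritParams cv_evaluate
#' @param n_random,n_bayes Search budgets (defaults 50 and 50).
#' @return The `cv_result` with maximal mean AUROC; attribute `"search"`
#'   holds the optimization history.
#' @export
search_technique <- function(technique, X, y, n_random = 50, n_bayes = 50,
                             repeats = 10, folds = 10, seed = 1) {
  cache <- new.env(parent = emptyenv())
  i <- 0L
  obj <- function(config) {
    i <<- i + 1L
    res <- cv_evaluate(technique, config, X, y, repeats, folds,
                       seed = seed + i)
    assign(sprintf("r%06d", i), res, envir = cache)
    res$mean_auroc
  }
  opt <- optimize_config(technique$space, obj, n_random, n_bayes, seed)
  best_i <- which.max(opt$history$value)
  res <- get(sprintf("r%06d", best_i), envir = cache)
  attr(res, "search") <- opt$history
  res
}

#' Fit the full base-model bundle
#'
#' Trains every technique on every feature set: hyper-parameter search under
#' repeated stratified CV, then a final refit on the full training subset at
#' the best configuration. With the 13 registered techniques and 4 feature
#' sets this yields 52 base models, each carrying its per-case
#' cross-validated scores and its mean CV AUROC (the ensembling weight).
#'
#' @param X Full training design matrix (with `column_info`).
#' @param y 0/1 outcome.
#' @param feature_sets Named list of column-name vectors (see
#'   [build_feature_sets()]).
#' @param techniques Registry subset from [technique_registry()].
#' @param n_random,n_bayes Search budgets.
#' @param repeats,folds CV geometry.
#' @param seed Integer seed.
#' @return Object of class `model_bundle`: list `models` with one entry per
#'   technique x feature set (`model`, `technique`, `feature_set`, `columns`,
#'   `config`, `mean_auroc`, `per_case_cv_score`).
#' @export
fit_bundle <- function(X, y, feature_sets, techniques = technique_registry(),
                       n_random = 50, n_bayes = 50, repeats = 10, folds = 10,
                       seed = 1) {
  models <- list()
  idx <- 0L
  for (set_name in names(feature_sets)) {
    cols <- feature_sets[[set_name]]
    Xs <- subset_design(X, cols)
    for (tech in techniques) {
      idx <- idx + 1L
      res <- tryCatch(
        search_technique(tech, Xs, y, n_random, n_bayes, repeats, folds,
                         seed = derive_seed(seed, paste(tech$name, set_name))),
        error = function(e) stop("model fit failed for ", tech$name, " on ",
                                 set_name, ": ", conditionMessage(e)))
      final <- with_seed(derive_seed(seed, paste("refit", tech$name, set_name)),
                         tech$fit(Xs, y, res$config))
      models[[idx]] <- list(model = final, technique = tech$name,
                            feature_set = set_name, columns = cols,
                            config = res$config, mean_auroc = res$mean_auroc,
                            per_case_cv_score = res$per_case_cv_score)
    }
  }
  names(models) <- vapply(models, function(m) paste(m$technique, m$feature_set,
                                                    sep = "."), character(1))
  structure(list(models = models, techniques = names(techniques),
                 feature_sets = names(feature_sets)),
            class = "model_bundle")
}

#' Per-model scores of a bundle on new cases
#'
#' @param object A `model_bundle`.
#' @param X Design matrix (full column universe; each model subsets its own
#'   columns).
#' @param ... Unused.
#' @return Numeric matrix, cases x models, scores in [0, 1].
#' @export
predict.model_bundle <- function(object, X, ...) {
  reg <- technique_registry()
  out <- sapply(object$models, function(m) {
    s <- reg[[m$technique]]$predict(m$model, subset_design(X, m$columns))
    pmin(pmax(as.numeric(s), 0), 1)
  })
  out <- matrix(out, nrow = nrow(X),
                dimnames = list(NULL, names(object$models)))
  out
}

#' @export
print.model_bundle <- function(x, ...) {
  w <- vapply(x$models, `[[`, numeric(1), "mean_auroc")
  cat(sprintf("Model bundle: %d models (%d techniques x %d feature sets)\n",
              length(x$models), length(x$techniques), length(x$feature_sets)))
  cat(sprintf("CV AUROC range: %.3f - %.3f\n", min(w), max(w)))
  invisible(x)
}
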