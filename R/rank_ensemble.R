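#' Fit a weighted rank-average ensemble
#'
#' For each base model, the training cases' cross-validated scores are ranked
#' (ties receive the mean of their tied positions) and rescaled to [0, 1] as
#' `(rank - 1) / (n - 1)`. The sorted score -> rescaled-rank table per model,
#' together with each model's cross-validated mean AUROC as its weight, is
#' the deployable predictor.
#'
#' @param cv_scores Numeric matrix, training subjects x models, of
#'   cross-validated scores.
#' @param weights Positive per-model weights (cross-validated mean AUROC);
#'   named or in column order.
#' @return Object of class `rank_ensemble`.
#' @export
fit_rank_ensemble <- function(cv_scores, weights) {
  cv_scores <- as.matrix(cv_scores)
  M <- ncol(cv_scores)
  n <- nrow(cv_scores)
  stopifnot(M >= 1, n >= 2, length(weights) == M, all(weights > 0))
  if (is.null(colnames(cv_scores)))
    colnames(cv_scores) <- paste0("model", seq_len(M))
  if (!is.null(names(weights))) weights <- weights[colnames(cv_scores)]
  tables <- vector("list", M)
  names(tables) <- colnames(cv_scores)
  rr <- matrix(NA_real_, n, M, dimnames = dimnames(cv_scores))
  for (m in seq_len(M)) {
    s <- cv_scores[, m]
    if (stats::sd(s) == 0) {
      warning("constant score vector for model '", colnames(cv_scores)[m],
              "'; all rescaled ranks set to 0.5")
      r <- rep(0.5, n)
    } else {
      r <- (rank(s, ties.method = "average") - 1) / (n - 1)
    }
    rr[, m] <- r
    ord <- order(s)
    tables[[m]] <- list(scores = s[ord], ranks = r[ord])
  }
  structure(list(tables = tables, weights = as.numeric(weights),
                 model_names = colnames(cv_scores), rescaled_ranks = rr,
                 n_train = n),
            class = "rank_ensemble")
}

#' Blended training scores of a fitted ensemble
#'
#' The weighted arithmetic mean of each training case's rescaled ranks:
#' `sum(w_m * rank_m) / sum(w_m)`, in [0, 1].
#'
#' @param ens A `rank_ensemble`.
#' @return Numeric vector, one blended score per training case.
#' @export
ensemble_train_scores <- function(ens) {
  as.numeric(ens$rescaled_ranks %*% ens$weights) / sum(ens$weights)
}

## Map new scores to the rescaled rank of the nearest stored train score for
## one model (binary search via findInterval); equidistant neighbours
## contribute the mean of their two rescaled ranks.
nearest_rank <- function(tab, s) {
  x <- tab$scores
  r <- tab$ranks
  n <- length(x)
  i <- findInterval(s, x)            # x[i] <= s < x[i+1]
  lo <- pmax(i, 1L)
  hi <- pmin(i + 1L, n)
  dlo <- abs(s - x[lo])
  dhi <- abs(x[hi] - s)
  out <- ifelse(dlo < dhi - 1e-15, r[lo],
                ifelse(dhi < dlo - 1e-15, r[hi], (r[lo] + r[hi]) / 2))
  ## exact hits on a tied score value: all tied entries share one rescaled
  ## rank by the mean-rank rule, so picking either neighbour is consistent
  out
}

#' Predict blended scores for new cases
#'
#' Per case and model, the stored training score nearest in absolute
#' difference is located and its rescaled rank substituted for the model's
#' raw score; equidistant neighbours get the mean of the two candidate
#' ranks. The weighted average of the substituted ranks (weights = CV AUROC)
#' is the final continuous prediction score.
#'
#' @param object A `rank_ensemble`.
#' @param new_scores Numeric matrix, cases x models, column names matching
#'   the ensemble's models (a vector is accepted for a single-model
#'   ensemble).
#' @param ... Unused.
#' @return Numeric vector of blended scores in [0, 1].
#' @export
predict.rank_ensemble <- function(object, new_scores, ...) {
  if (is.null(dim(new_scores))) new_scores <- matrix(new_scores, ncol = 1)
  M <- length(object$tables)
  if (ncol(new_scores) != M)
    stop("new_scores has ", ncol(new_scores), " columns; ensemble has ", M,
         " models")
  if (!is.null(colnames(new_scores))) {
    missing <- setdiff(object$model_names, colnames(new_scores))
    if (length(missing))
      stop("missing model column(s): ", paste(missing, collapse = ", "))
    new_scores <- new_scores[, object$model_names, drop = FALSE]
  }
  R <- vapply(seq_len(M),
              function(m) nearest_rank(object$tables[[m]], new_scores[, m]),
              numeric(nrow(new_scores)))
  R <- matrix(R, nrow = nrow(new_scores))
  as.numeric(R %*% object$weights) / sum(object$weights)
}

#' @export
print.rank_ensemble <- function(x, ...) {
  cat(sprintf("Weighted rank-average ensemble: %d models, %d training cases\n",
              length(x$tables), x$n_train))
  cat(sprintf("Weights (CV AUROC): %.3f - %.3f\n",
              min(x$weights), max(x$weights)))
  invisible(x)
}
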