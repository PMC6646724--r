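#' Pooled single-feature AUROC under the site-independent protocol
#'
#' For one post-preprocessing design column: in each of the plan's
#' replications, preprocessing is fitted on the four training subsets, a
#' logistic regression on the single column is trained, and the held-out
#' subset is scored; the five test score vectors are pooled and the AUROC
#' with its stratified BCa CI computed. A column absent from some
#' replication's design (e.g. dropped by preprocessing) is reported as
#' unavailable rather than an error.
#'
#' @param cohort A `cohort_table`.
#' @param plan A `split_plan`.
#' @param column Design-matrix column name (post-preprocessing).
#' @param seed Integer seed (bootstrap).
#' @param resamples Bootstrap resamples.
#' @param missing_cutoff,r_threshold,eig_threshold Preprocessing settings.
#' @return List: `column`, `auroc`, `ci` (or `available = FALSE`).
#' @export
single_feature_auroc <- function(cohort, plan, column, seed = 1,
                                 resamples = 10000, missing_cutoff = 0.20,
                                 r_threshold = 0.75, eig_threshold = 1.0) {
  sub <- subset_of(plan, cohort)
  pieces <- list()
  for (r in seq_len(plan$k)) {
    train <- cohort_subset(cohort, sub != r)
    test <- cohort_subset(cohort, sub == r)
    pp <- fit_preprocess(train, missing_cutoff, r_threshold, eig_threshold,
                         fitted_on = paste0("rep", r))
    Xtr <- predict(pp, train)
    if (!column %in% colnames(Xtr))
      return(list(column = column, available = FALSE))
    Xte <- predict(pp, test)
    d <- data.frame(y = train$outcome, x = Xtr[, column])
    m <- suppressWarnings(stats::glm(y ~ x, data = d, family = stats::binomial()))
    s <- suppressWarnings(stats::predict(m, data.frame(x = Xte[, column]),
                                         type = "response"))
    pieces[[r]] <- data.frame(subject_id = test$subject_id, score = s,
                              label = test$outcome)
  }
  pooled <- do.call(rbind, pieces)
  a <- auroc(pooled$score, pooled$label)
  ci <- bca_ci(pooled$score, pooled$label, resamples = resamples, seed = seed)
  list(column = column, available = TRUE, auroc = a, ci = ci)
}

#' Rank all features by single-feature pooled AUROC
#'
#' Evaluates every post-preprocessing design column under
#' [single_feature_auroc()] and orders them by descending AUROC. A feature
#' is flagged significant when the lower CI bound is strictly above 0.5.
#'
#' @inheritParams single_feature_auroc
#' @return Object of class `importance_report`: data.frame with `feature`,
#'   `auroc`, `ci_lo`, `ci_hi`, `significant`.
#' @export
importance_report <- function(cohort, plan, seed = 1, resamples = 10000,
                              missing_cutoff = 0.20, r_threshold = 0.75,
                              eig_threshold = 1.0) {
  sub <- subset_of(plan, cohort)
  pp1 <- fit_preprocess(cohort_subset(cohort, sub != 1), missing_cutoff,
                        r_threshold, eig_threshold)
  columns <- colnames(predict(pp1, cohort_subset(cohort, sub != 1)))
  rows <- list()
  for (j in seq_along(columns)) {
    res <- single_feature_auroc(cohort, plan, columns[j],
                                seed = seed + j, resamples = resamples,
                                missing_cutoff = missing_cutoff,
                                r_threshold = r_threshold,
                                eig_threshold = eig_threshold)
    rows[[j]] <- if (isTRUE(res$available)) {
      data.frame(feature = columns[j], auroc = res$auroc,
                 ci_lo = res$ci$lo, ci_hi = res$ci$hi,
                 significant = res$ci$lo > 0.5)
    } else {
      data.frame(feature = columns[j], auroc = NA_real_, ci_lo = NA_real_,
                 ci_hi = NA_real_, significant = NA)
    }
  }
  out <- do.call(rbind, rows)
  out <- out[order(-out$auroc), ]
  rownames(out) <- NULL
  structure(out, class = c("importance_report", "data.frame"))
}

#' @export
print.importance_report <- function(x, ...) {
  cat("Single-feature pooled test AUROC (descending):\n")
  print(as.data.frame(x), row.names = FALSE, digits = 3)
  invisible(x)
}
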