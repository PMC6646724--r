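#' Area under the ROC curve
#'
#' Mann-Whitney estimator: the probability that a randomly selected positive
#' case scores higher than a randomly selected negative case, with tied pairs
#' counted 1/2.
#'
#' @param scores Numeric score vector.
#' @param labels 0/1 outcome vector.
#' @return AUROC in [0, 1].
#' @export
auroc <- function(scores, labels) {
  y <- as.integer(labels)
  n1 <- as.numeric(sum(y == 1))
  n0 <- as.numeric(sum(y == 0))
  if (n1 == 0 || n0 == 0) stop("both classes must be present to compute AUROC")
  r <- rank(scores, ties.method = "average")
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

## sensitivity/specificity at every candidate threshold in one sweep.
## rule: score >= threshold -> positive.
threshold_profile <- function(scores, labels, thresholds) {
  y <- as.integer(labels)
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  sens <- vapply(thresholds, function(t) sum(scores >= t & y == 1) / n1, numeric(1))
  spec <- vapply(thresholds, function(t) sum(scores < t & y == 0) / n0, numeric(1))
  data.frame(threshold = thresholds, sensitivity = sens, specificity = spec)
}

ba_candidates <- function(scores) {
  u <- sort(unique(scores))
  if (length(u) == 1) return(c(-Inf, Inf))
  c(-Inf, (u[-length(u)] + u[-1]) / 2, Inf)
}

#' Threshold maximizing balanced accuracy
#'
#' Candidate thresholds are the midpoints between consecutive distinct sorted
#' scores plus -Inf/+Inf sentinels; the candidate with maximal
#' (sensitivity + specificity) / 2 is returned, ties resolved toward the
#' largest threshold.
#'
#' @inheritParams auroc
#' @return The selected threshold (classification rule: score >= threshold).
#' @export
best_ba_threshold <- function(scores, labels) {
  cand <- ba_candidates(scores)
  prof <- threshold_profile(scores, labels, cand)
  ba <- (prof$sensitivity + prof$specificity) / 2
  best <- which(ba >= max(ba) - 1e-12)
  cand[best[length(best)]]
}

#' Threshold achieving a target sensitivity
#'
#' The largest observed score value whose sensitivity (score >= threshold)
#' is at least `target` -- i.e. the most specific threshold subject to the
#' sensitivity floor. Target 1 is always achievable at the minimum positive
#' score.
#'
#' @inheritParams auroc
#' @param target Sensitivity floor in (0, 1].
#' @return The selected threshold.
#' @export
sensitivity_threshold <- function(scores, labels, target) {
  stopifnot(target > 0, target <= 1)
  cand <- sort(unique(scores))
  prof <- threshold_profile(scores, labels, cand)
  ok <- prof$sensitivity >= target - 1e-12
  max(cand[ok])
}

#' Confusion metrics at a threshold
#'
#' Classification rule: score >= threshold is a predicted converter.
#' Balanced accuracy is (sensitivity + specificity)/2 and F1 the harmonic
#' mean of sensitivity and positive predictive value. With no predicted
#' positives, PPV and F1 are `NaN` and the record is flagged.
#'
#' @inheritParams auroc
#' @param threshold Decision threshold.
#' @return One-row data.frame: sensitivity, specificity, ppv, npv,
#'   balanced_accuracy, f1, plus counts and a `degenerate` flag.
#' @export
confusion_metrics <- function(scores, labels, threshold) {
  y <- as.integer(labels)
  pred <- as.integer(scores >= threshold)
  tp <- sum(pred == 1 & y == 1); fp <- sum(pred == 1 & y == 0)
  fn <- sum(pred == 0 & y == 1); tn <- sum(pred == 0 & y == 0)
  sens <- tp / (tp + fn)
  spec <- tn / (tn + fp)
  ppv <- if (tp + fp > 0) tp / (tp + fp) else NaN
  npv <- if (tn + fn > 0) tn / (tn + fn) else NaN
  data.frame(threshold = threshold, sensitivity = sens, specificity = spec,
             ppv = ppv, npv = npv,
             balanced_accuracy = balanced_accuracy(sens, spec),
             f1 = f1_score(sens, ppv),
             tp = tp, fp = fp, fn = fn, tn = tn,
             degenerate = (tp + fp == 0) || (tn + fn == 0))
}

#' Balanced accuracy from sensitivity and specificity
#' @param sensitivity,specificity Proportions in [0, 1].
#' @return `(sensitivity + specificity) / 2`.
#' @export
balanced_accuracy <- function(sensitivity, specificity) {
  (sensitivity + specificity) / 2
}

#' F1 score from sensitivity and positive predictive value
#' @param sensitivity,ppv Proportions in [0, 1].
#' @return Harmonic mean `2 * sens * ppv / (sens + ppv)`.
#' @export
f1_score <- function(sensitivity, ppv) {
  2 * sensitivity * ppv / (sensitivity + ppv)
}

#' Screening yield of a fully sensitive threshold
#'
#' At 100% sensitivity, every true converter is flagged; the fraction of the
#' screened population confidently ruled out is the specificity times the
#' non-conversion rate.
#'
#' @param specificity Specificity achieved at the fully sensitive threshold.
#' @param conversion_rate Expected conversion rate in the screened
#'   population.
#' @return Proportion of subjects ruled out.
#' @export
screening_yield <- function(specificity, conversion_rate) {
  specificity * (1 - conversion_rate)
}

#' Stratified BCa bootstrap confidence interval
#'
#' Resamples with replacement within each outcome class (strata = outcome),
#' recomputes the statistic per resample, and forms the bias-corrected and
#' accelerated interval: bias constant `z0` from the fraction of bootstrap
#' statistics below the point estimate, acceleration `a` from the jackknife
#' (leave-one-out over all subjects) skewness. A degenerate bootstrap
#' distribution (all resampled values equal) falls back to the percentile
#' interval with a warning; the returned interval always contains the point
#' estimate.
#'
#' @inheritParams auroc
#' @param statistic Function(scores, labels) -> numeric (default [auroc()]).
#' @param resamples Bootstrap resamples (default 10000).
#' @param level Confidence level (default 0.95).
#' @param seed Integer seed.
#' @return List: `lo`, `hi`, `level`, `method`, `resamples`, `estimate`,
#'   `degenerate`.
#' @export
bca_ci <- function(scores, labels, statistic = auroc, resamples = 10000,
                   level = 0.95, seed = 1) {
  y <- as.integer(labels)
  stopifnot(sum(y == 1) > 0, sum(y == 0) > 0)
  est <- statistic(scores, y)
  i1 <- which(y == 1); i0 <- which(y == 0)
  boot_stats <- with_seed(derive_seed(seed, "bootstrap"), {
    vapply(seq_len(resamples), function(b) {
      idx <- c(sample(i1, length(i1), replace = TRUE),
               sample(i0, length(i0), replace = TRUE))
      statistic(scores[idx], y[idx])
    }, numeric(1))
  })
  alpha <- (1 - level) / 2
  degen <- stats::sd(boot_stats) == 0 || !is.finite(stats::sd(boot_stats))
  prop_below <- mean(boot_stats < est) + 0.5 * mean(boot_stats == est)
  if (degen || prop_below <= 0 || prop_below >= 1) {
    if (!degen)
      warning("bias correction undefined (point estimate outside bootstrap range); ",
              "falling back to percentile interval")
    q <- stats::quantile(boot_stats, c(alpha, 1 - alpha), names = FALSE,
                         type = 6)
    return(list(lo = min(q[1], est), hi = max(q[2], est), level = level,
                method = if (degen) "degenerate" else "percentile",
                resamples = resamples, estimate = est, degenerate = degen))
  }
  z0 <- stats::qnorm(prop_below)
  n <- length(y)
  jack <- vapply(seq_len(n), function(i) statistic(scores[-i], y[-i]), numeric(1))
  jm <- mean(jack)
  denom <- sum((jm - jack)^2)^1.5
  a <- if (denom == 0) 0 else sum((jm - jack)^3) / (6 * denom)
  adj <- function(q) {
    zq <- stats::qnorm(q)
    stats::pnorm(z0 + (z0 + zq) / (1 - a * (z0 + zq)))
  }
  q <- stats::quantile(boot_stats, c(adj(alpha), adj(1 - alpha)),
                       names = FALSE, type = 6)
  list(lo = min(q[1], est), hi = max(q[2], est), level = level, method = "BCa",
       resamples = resamples, estimate = est, degenerate = FALSE)
}

#' Calibrate the threshold family on one replication's training scores
#'
#' @inheritParams auroc
#' @param sensitivity_targets Sensitivity floors (default the seven-level
#'   family 1, 0.975, 0.95, 0.90, 0.85, 0.80, 0.75).
#' @return List: `best_ba` threshold and named `at_sensitivity` thresholds.
#' @export
calibrate_thresholds <- function(scores, labels,
                                 sensitivity_targets = c(1, 0.975, 0.95, 0.90,
                                                         0.85, 0.80, 0.75)) {
  list(best_ba = best_ba_threshold(scores, labels),
       at_sensitivity = stats::setNames(
         vapply(sensitivity_targets, function(t)
           sensitivity_threshold(scores, labels, t), numeric(1)),
         format(sensitivity_targets, trim = TRUE, drop0trailing = TRUE)))
}

#' Average per-replication threshold families
#'
#' The final deployable thresholds are the arithmetic means of the
#' per-replication calibrated thresholds.
#'
#' @param threshold_list List of outputs of [calibrate_thresholds()].
#' @return Object of class `threshold_set` with `best_ba`, `at_sensitivity`
#'   and the retained `per_replication` values.
#' @export
average_thresholds <- function(threshold_list) {
  ba <- mean(vapply(threshold_list, `[[`, numeric(1), "best_ba"))
  sens_mat <- sapply(threshold_list, `[[`, "at_sensitivity")
  at <- rowMeans(matrix(sens_mat, nrow = nrow(as.matrix(sens_mat)),
                        dimnames = list(rownames(as.matrix(sens_mat)), NULL)))
  structure(list(best_ba = ba, at_sensitivity = at,
                 per_replication = threshold_list),
            class = "threshold_set")
}

#' Pool replication test scores and evaluate
#'
#' Concatenates the per-replication test score vectors (which must partition
#' the cohort's subjects), computes the pooled AUROC with its stratified BCa
#' bootstrap CI, and emits the confusion-metric family at the averaged
#' best-balanced-accuracy threshold and at each sensitivity-target
#' threshold.
#'
#' @param replication_scores List (one element per replication) of
#'   data.frames with `subject_id`, `score`, `label`.
#' @param thresholds A `threshold_set`.
#' @param resamples Bootstrap resamples (default 10000).
#' @param seed Integer seed.
#' @return Object of class `evaluation_report`: `pooled` (data.frame),
#'   `auroc`, `auroc_ci`, `metrics` (one row per threshold).
#' @export
pool_and_report <- function(replication_scores, thresholds, resamples = 10000,
                            seed = 1) {
  ids <- unlist(lapply(replication_scores, `[[`, "subject_id"))
  if (anyDuplicated(ids))
    stop("overlapping subjects across replications; test subsets must partition the cohort")
  pooled <- do.call(rbind, lapply(seq_along(replication_scores), function(r)
    cbind(replication_scores[[r]], replication = r)))
  a <- auroc(pooled$score, pooled$label)
  ci <- bca_ci(pooled$score, pooled$label, resamples = resamples, seed = seed)
  rows <- list()
  for (nm in names(thresholds$at_sensitivity)) {
    row <- confusion_metrics(pooled$score, pooled$label,
                             thresholds$at_sensitivity[[nm]])
    row <- cbind(data.frame(rule = paste0("sensitivity_", nm)), row)
    rows[[length(rows) + 1]] <- row
  }
  row <- confusion_metrics(pooled$score, pooled$label, thresholds$best_ba)
  rows[[length(rows) + 1]] <- cbind(data.frame(rule = "best_balanced_accuracy"), row)
  metrics <- do.call(rbind, rows)
  rownames(metrics) <- NULL
  structure(list(pooled = pooled, auroc = a, auroc_ci = ci, metrics = metrics),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("Pooled test AUROC: %.3f (%.0f%% BCa CI %.3f-%.3f, %d resamples)\n",
              x$auroc, 100 * x$auroc_ci$level, x$auroc_ci$lo, x$auroc_ci$hi,
              x$auroc_ci$resamples))
  print(x$metrics[, c("rule", "sensitivity", "specificity", "ppv", "npv",
                      "balanced_accuracy", "f1")], row.names = FALSE,
        digits = 3)
  invisible(x)
}
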