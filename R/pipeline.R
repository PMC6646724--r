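#' Protocol configuration
#'
#' Bundles every protocol constant. The `"full"` profile mirrors the
#' published study design: 13 techniques, 50 random + 50 Bayesian
#' hyper-parameter configurations, 10x10 repeated stratified CV, 10000
#' bootstrap resamples, the seven-level sensitivity-target family. The
#' `"desk"` profile is a documented reduction for interactive use and
#' testing: 3 fast techniques (LR, EN, kNN), 5+5 search budget, 5-fold x
#' 2-repeat CV, a 150-tree RFE forest and 2000 resamples.
#'
#' @param profile `"full"` or `"desk"`.
#' @param ... Overrides for any config field.
#' @return Object of class `run_config`.
#' @export
run_config <- function(profile = c("full", "desk"), ...) {
  profile <- match.arg(profile)
  cfg <- list(
    profile = profile,
    techniques = names(technique_registry()),
    n_random = 50, n_bayes = 50,
    cv_repeats = 10, cv_folds = 10,
    missing_cutoff = 0.20, r_threshold = 0.75, eig_threshold = 1.0,
    filter_alpha = 0.05, rfe_folds = 10, rfe_ntree = 500,
    sensitivity_targets = c(1, 0.975, 0.95, 0.90, 0.85, 0.80, 0.75),
    resamples = 10000,
    importance = TRUE
  )
  if (profile == "desk") {
    cfg$techniques <- c("LR", "EN", "kNN")
    cfg$n_random <- 5; cfg$n_bayes <- 5
    cfg$cv_repeats <- 2; cfg$cv_folds <- 5
    cfg$rfe_folds <- 5; cfg$rfe_ntree <- 150
    cfg$resamples <- 2000
  }
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown)) stop("unknown config field(s): ", paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  structure(cfg, class = "run_config")
}

## Fit one replication from its training cohort alone. The held-out subset
## is never passed in: blindness is structural, not just asserted.
fit_replication <- function(train, config, seed, label) {
  pp <- fit_preprocess(train, config$missing_cutoff, config$r_threshold,
                       config$eig_threshold, fitted_on = label)
  X <- predict(pp, train)
  y <- train$outcome
  fsets <- build_feature_sets(X, y, alpha = config$filter_alpha,
                              folds = config$rfe_folds,
                              seed = derive_seed(seed, paste("select", label)),
                              ntree = config$rfe_ntree)
  bundle <- fit_bundle(X, y, fsets,
                       techniques = technique_registry(config$techniques),
                       n_random = config$n_random, n_bayes = config$n_bayes,
                       repeats = config$cv_repeats, folds = config$cv_folds,
                       seed = derive_seed(seed, paste("zoo", label)))
  cvs <- sapply(bundle$models, `[[`, "per_case_cv_score")
  w <- vapply(bundle$models, `[[`, numeric(1), "mean_auroc")
  ens <- fit_rank_ensemble(cvs, w)
  blended <- ensemble_train_scores(ens)
  thr <- calibrate_thresholds(blended, y, config$sensitivity_targets)
  list(label = label, preprocess = pp, feature_sets = fsets, bundle = bundle,
       ensemble = ens, train_blended = blended, thresholds = thr)
}

#' Fit the site-independent ensemble prognosis model
#'
#' End-to-end orchestration of the five-replication protocol on a cohort:
#' partition the recruitment sites into k site-independent, outcome-
#' stratified subsets; for each replication fit preprocessing, the four
#' feature sets, the technique x feature-set model bundle and the weighted
#' rank-average ensemble on the k-1 training subsets, calibrate the
#' threshold family on the training blended scores, and score the blind
#' held-out subset; finally average the thresholds, pool the five test score
#' vectors, and evaluate (AUROC with BCa CI, confusion-metric family, and
#' optionally the single-feature importance ranking).
#'
#' @param cohort A `cohort_table`.
#' @param constraints A `split_constraints` (default `split_constraints()`).
#' @param config A `run_config` (default full profile).
#' @param seed Master integer seed; fans out to per-stage seeds.
#' @param plan Optional pre-computed `split_plan` (skips the search).
#' @return Object of class `mci_prognosis`.
#' @export
mci_prognosis <- function(cohort, constraints = split_constraints(),
                          config = run_config("full"), seed = 1, plan = NULL) {
  if (is.null(plan)) {
    plan <- search_split(cohort, constraints, seed = derive_seed(seed, "split"))
    if (inherits(plan, "split_failure"))
      stop("site partition failed (", plan$status, "); best coverage ",
           sprintf("%.1f%%", 100 * plan$best_coverage),
           " - relax the bands or raise n_candidates")
  }
  sub <- subset_of(plan, cohort)
  reps <- vector("list", plan$k)
  test_scores <- vector("list", plan$k)
  for (r in seq_len(plan$k)) {
    train <- cohort_subset(cohort, sub != r)
    reps[[r]] <- fit_replication(train, config, seed, label = LETTERS[r])
    test <- cohort_subset(cohort, sub == r)
    S <- predict(reps[[r]]$bundle, predict(reps[[r]]$preprocess, test))
    blended <- predict(reps[[r]]$ensemble, S)
    test_scores[[r]] <- data.frame(subject_id = test$subject_id,
                                   score = blended, label = test$outcome)
  }
  thr <- average_thresholds(lapply(reps, `[[`, "thresholds"))
  report <- pool_and_report(test_scores, thr, resamples = config$resamples,
                            seed = derive_seed(seed, "threshold"))
  imp <- NULL
  if (isTRUE(config$importance)) {
    imp <- importance_report(cohort, plan,
                             seed = derive_seed(seed, "importance"),
                             resamples = config$resamples,
                             missing_cutoff = config$missing_cutoff,
                             r_threshold = config$r_threshold,
                             eig_threshold = config$eig_threshold)
  }
  structure(list(plan = plan, replications = reps, thresholds = thr,
                 report = report, importance = imp, config = config,
                 seed = seed),
            class = "mci_prognosis")
}

#' Run the full protocol and write its artifacts
#'
#' Convenience wrapper around [mci_prognosis()] that writes `report.json`,
#' `metrics.csv` and (when enabled) `importance.csv` into a run directory.
#'
#' @inheritParams mci_prognosis
#' @param out_dir Output directory (created if absent).
#' @return The fitted `mci_prognosis`, invisibly; artifacts on disk.
#' @export
run_protocol <- function(cohort, out_dir, constraints = split_constraints(),
                         config = run_config("full"), seed = 1, plan = NULL) {
  fit <- mci_prognosis(cohort, constraints, config, seed, plan)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  rep_json <- list(
    auroc = fit$report$auroc,
    auroc_ci = fit$report$auroc_ci[c("lo", "hi", "level", "method", "resamples")],
    thresholds = list(best_ba = fit$thresholds$best_ba,
                      at_sensitivity = as.list(fit$thresholds$at_sensitivity)),
    plan = split(names(fit$plan$assignment), fit$plan$assignment),
    seed = fit$seed, profile = fit$config$profile
  )
  jsonlite::write_json(rep_json, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  utils::write.csv(fit$report$metrics, file.path(out_dir, "metrics.csv"),
                   row.names = FALSE)
  if (!is.null(fit$importance))
    utils::write.csv(as.data.frame(fit$importance),
                     file.path(out_dir, "importance.csv"), row.names = FALSE)
  invisible(fit)
}

#' Predict conversion risk for new cases
#'
#' Each replication's pipeline (preprocessing, base models, rank ensemble)
#' scores the new cases; the final score is the mean of the five blended
#' scores (or a single replication's, if requested). With
#' `type = "class"`, the averaged best-balanced-accuracy threshold
#' dichotomizes the score.
#'
#' @param object A fitted `mci_prognosis`.
#' @param newdata A `cohort_table` with the training schema.
#' @param type `"score"` (default) or `"class"`.
#' @param replication `"average"` or a replication index.
#' @param ... Unused.
#' @return Numeric scores in [0, 1], or 0/1 class predictions.
#' @export
predict.mci_prognosis <- function(object, newdata, type = c("score", "class"),
                                  replication = "average", ...) {
  type <- match.arg(type)
  score_one <- function(rep) {
    S <- predict(rep$bundle, predict(rep$preprocess, newdata))
    predict(rep$ensemble, S)
  }
  s <- if (identical(replication, "average")) {
    rowMeans(vapply(object$replications, score_one, numeric(nrow(newdata))))
  } else {
    score_one(object$replications[[replication]])
  }
  if (type == "class") as.integer(s >= object$thresholds$best_ba) else s
}

#' @export
print.mci_prognosis <- function(x, ...) {
  cat("Site-independent weighted rank-average ensemble prognosis\n")
  cat(sprintf("  %d replications, %d base models each (%s profile)\n",
              length(x$replications),
              length(x$replications[[1]]$bundle$models), x$config$profile))
  cat(sprintf("  Pooled test AUROC %.3f (%.0f%% CI %.3f-%.3f)\n",
              x$report$auroc, 100 * x$report$auroc_ci$level,
              x$report$auroc_ci$lo, x$report$auroc_ci$hi))
  invisible(x)
}

#' @export
summary.mci_prognosis <- function(object, ...) {
  print(object)
  cat("\nPer-subset composition:\n")
  print(object$plan$counts, row.names = FALSE)
  cat("\nTest metrics by threshold rule:\n")
  print(object$report$metrics[, c("rule", "sensitivity", "specificity", "ppv",
                                  "npv", "balanced_accuracy", "f1")],
        row.names = FALSE, digits = 3)
  if (!is.null(object$importance)) {
    cat("\nTop single-feature AUROCs:\n")
    print(utils::head(as.data.frame(object$importance), 5),
          row.names = FALSE, digits = 3)
  }
  invisible(object)
}

#' ROC curve of the pooled test predictions
#'
#' @param x A fitted `mci_prognosis`.
#' @param ... Passed to [plot()].
#' @export
plot.mci_prognosis <- function(x, ...) {
  p <- x$report$pooled
  thr <- sort(unique(p$score), decreasing = TRUE)
  sens <- vapply(thr, function(t) mean(p$score[p$label == 1] >= t), numeric(1))
  fpr <- vapply(thr, function(t) mean(p$score[p$label == 0] >= t), numeric(1))
  plot(c(0, fpr, 1), c(0, sens, 1), type = "l",
       xlab = "False positive rate", ylab = "Sensitivity",
       main = sprintf("Pooled test ROC (AUROC %.3f)", x$report$auroc), ...)
  graphics::abline(0, 1, lty = 3)
  invisible(x)
}
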