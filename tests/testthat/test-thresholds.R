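test_that("AUROC equals the all-pairs oracle on fixtures with ties", {
  expect_identical(auroc(c(0.2, 0.4, 0.6, 0.8), c(0, 0, 1, 1)), 1)
  expect_identical(auroc(c(0.2, 0.4, 0.6, 0.8), c(0, 1, 0, 1)), 0.75)
  set.seed(17)
  for (rep in 1:10) {
    n <- sample(20:200, 1)
    s <- round(runif(n), 2)          # rounding forces ties
    y <- rbinom(n, 1, 0.4)
    if (length(unique(y)) < 2) next
    expect_equal(auroc(s, y), auroc_pairs(s, y), tolerance = 1e-12)
  }
  expect_error(auroc(1:5, rep(1, 5)), "both classes")
})

test_that("AUROC agrees with an established ROC implementation", {
  set.seed(23)
  s <- rnorm(150)
  y <- rbinom(150, 1, plogis(s))
  expect_equal(auroc(s, y),
               as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE))),
               tolerance = 1e-12)
})

test_that("random scores on shuffled labels sit at chance", {
  set.seed(31)
  s <- runif(10000)
  y <- sample(rep(0:1, 5000))
  expect_lt(abs(auroc(s, y) - 0.5), 0.02)
})

test_that("best balanced-accuracy threshold uses midpoints and the tie rule", {
  thr <- best_ba_threshold(c(0.1, 0.2, 0.8, 0.9), c(0, 0, 1, 1))
  expect_identical(thr, 0.5)
  cm <- confusion_metrics(c(0.1, 0.2, 0.8, 0.9), c(0, 0, 1, 1), thr)
  expect_identical(cm$balanced_accuracy, 1)
  ## all scores equal: any threshold gives BA 0.5; the largest-threshold tie
  ## rule labels everyone negative
  expect_identical(best_ba_threshold(rep(0.4, 6), c(1, 0, 0, 1, 0, 0)), Inf)
  ## exhaustive-scan oracle on a 20-point fixture
  set.seed(41)
  s <- round(runif(20), 2)
  y <- rbinom(20, 1, 0.4)
  thr20 <- best_ba_threshold(s, y)
  grid <- sort(unique(c(-Inf, Inf, s, s - 1e-6, s + 1e-6)))
  ba_at <- function(t) {
    sens <- mean(s[y == 1] >= t); spec <- mean(s[y == 0] < t)
    (sens + spec) / 2
  }
  best_grid <- max(vapply(grid, ba_at, numeric(1)))
  expect_equal(ba_at(thr20), best_grid, tolerance = 1e-12)
})

test_that("sensitivity-targeted thresholds honour the floor and maximize specificity", {
  ## target 1: threshold lands on the minimum positive score
  s <- c(0.1, 0.3, 0.8, 0.85, 0.9, 0.95)
  y <- c(0, 0, 0, 1, 1, 1)
  expect_identical(sensitivity_threshold(s, y, 1), 0.85)
  ## enumeration oracle on a 12-point fixture with 4 positives at target .75:
  ## keep >= 3 positives, choose the largest such threshold
  s12 <- c(0.05, 0.1, 0.2, 0.3, 0.42, 0.48, 0.55, 0.6, 0.62, 0.7, 0.8, 0.9)
  y12 <- c(0, 0, 0, 0, 1, 0, 0, 1, 0, 1, 0, 1)
  t75 <- sensitivity_threshold(s12, y12, 0.75)
  expect_identical(t75, 0.6)
  expect_gte(mean(s12[y12 == 1] >= t75), 0.75)
  ## monotone in the target: a laxer floor never lowers the threshold
  targets <- c(1, 0.975, 0.95, 0.9, 0.85, 0.8, 0.75)
  thr <- vapply(targets, function(t) sensitivity_threshold(s12, y12, t),
                numeric(1))
  expect_true(all(diff(thr) >= 0))
})

test_that("confusion metrics reproduce the printed identities", {
  expect_equal(round(balanced_accuracy(0.777, 0.799), 3), 0.788)
  expect_equal(round(f1_score(0.777, 0.683), 3), 0.727)
  expect_equal(screening_yield(0.402, 0.20), 0.3216)
  ## perfect classifier fixture: every metric is 1
  cm <- confusion_metrics(c(0.1, 0.2, 0.9, 1), c(0, 0, 1, 1), 0.5)
  expect_equal(cm$sensitivity, 1); expect_equal(cm$specificity, 1)
  expect_equal(cm$ppv, 1); expect_equal(cm$npv, 1)
  expect_equal(cm$balanced_accuracy, 1); expect_equal(cm$f1, 1)
  ## no predicted positives: PPV undefined and flagged
  cm0 <- confusion_metrics(c(0.1, 0.2, 0.3, 0.4), c(0, 0, 1, 1), 10)
  expect_true(is.nan(cm0$ppv))
  expect_true(cm0$degenerate)
})

test_that("threshold calibration averages across replications coherently", {
  set.seed(51)
  reps <- lapply(1:5, function(r) {
    s <- runif(80)
    y <- rbinom(80, 1, 0.3 + 0.4 * s)
    if (length(unique(y)) < 2) y[1:2] <- 0:1
    calibrate_thresholds(s, y)
  })
  avg <- average_thresholds(reps)
  expect_equal(avg$best_ba, mean(vapply(reps, `[[`, numeric(1), "best_ba")))
  expect_equal(unname(avg$at_sensitivity["1"]),
               mean(vapply(reps, function(x) x$at_sensitivity[["1"]],
                           numeric(1))))
  ## per-replication families are complete and monotone in the target
  for (r in 1:5) {
    expect_length(reps[[r]]$at_sensitivity, 7)
    expect_true(all(diff(reps[[r]]$at_sensitivity) >= 0))
  }
})

test_that("BCa interval brackets the estimate and handles degeneracy", {
  ## separable fixture: every resample has AUROC 1, CI collapses
  s <- c(0.1, 0.2, 0.3, 0.8, 0.9, 1.0)
  y <- c(0, 0, 0, 1, 1, 1)
  ci <- bca_ci(s, y, resamples = 200, seed = 3)
  expect_identical(ci$lo, 1); expect_identical(ci$hi, 1)
  expect_identical(ci$method, "degenerate")
  ## generic fixtures: the point estimate always lies inside the interval
  set.seed(61)
  for (rep in 1:5) {
    n <- 80
    sc <- rnorm(n)
    yy <- rbinom(n, 1, plogis(sc))
    if (length(unique(yy)) < 2) next
    ci <- bca_ci(sc, yy, resamples = 400, seed = rep)
    expect_lte(ci$lo, ci$estimate); expect_gte(ci$hi, ci$estimate)
    expect_identical(ci$method, "BCa")
  }
})

test_that("BCa endpoints agree with the boot package on a common fixture", {
  set.seed(71)
  n <- 120
  s <- rnorm(n, 0.8 * rep(c(0, 1), n / 2))
  y <- rep(c(0L, 1L), n / 2)
  ours <- bca_ci(s, y, resamples = 4000, seed = 5)
  bt <- boot::boot(data.frame(s = s, y = y),
                   function(d, i) auroc(d$s[i], d$y[i]),
                   R = 4000, strata = y)
  bci <- boot::boot.ci(bt, type = "bca")$bca[4:5]
  expect_lt(abs(ours$lo - bci[1]), 0.03)
  expect_lt(abs(ours$hi - bci[2]), 0.03)
})

test_that("pooled evaluation reports eight threshold rows over a partition", {
  set.seed(81)
  reps <- lapply(1:5, function(r) {
    n <- 30
    data.frame(subject_id = sprintf("r%d_s%02d", r, 1:n),
               score = runif(n), label = rbinom(n, 1, 0.36))
  })
  train_s <- runif(200); train_y <- rbinom(200, 1, 0.3 + 0.4 * train_s)
  thr <- average_thresholds(lapply(1:5, function(r)
    calibrate_thresholds(train_s, train_y)))
  rep <- pool_and_report(reps, thr, resamples = 200, seed = 2)
  expect_identical(nrow(rep$pooled), 150L)
  expect_identical(nrow(rep$metrics), 8L)
  expect_true(all(c("sensitivity", "specificity", "ppv", "npv",
                    "balanced_accuracy", "f1") %in% names(rep$metrics)))
  expect_true(rep$auroc >= rep$auroc_ci$lo && rep$auroc <= rep$auroc_ci$hi)
  ## overlapping subjects across replications are an integrity error
  reps_bad <- reps; reps_bad[[2]]$subject_id <- reps[[1]]$subject_id
  expect_error(pool_and_report(reps_bad, thr, resamples = 50), "overlap")
})
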