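## small cohort builder for transformation tests
pp_cohort <- function(df, schema) {
  cohort_table(sprintf("s%03d", seq_len(nrow(df))),
               rep(c("A", "B"), length.out = nrow(df)),
               rep(c(1, 0), length.out = nrow(df)), df, schema)
}

test_that("missingness exclusion uses a strict cutoff", {
  n <- 550
  df <- data.frame(
    digit = c(rep(NA_real_, 290), rnorm(n - 290)),   # 52.73% -> dropped
    atcut = c(rep(NA_real_, 110), rnorm(n - 110)),   # exactly 20% -> kept
    low = c(NA_real_, rnorm(n - 1)),                 # 0.18% -> kept
    stringsAsFactors = FALSE
  )
  sch <- cohort_schema(feature_spec("digit", "continuous"),
                       feature_spec("atcut", "continuous"),
                       feature_spec("low", "continuous"))
  res <- drop_high_missing(pp_cohort(df, sch), cutoff = 0.20)
  expect_identical(res$dropped$feature, "digit")
  expect_setequal(names(attr(res$table, "schema")), c("atcut", "low"))
})

test_that("perfectly correlated features collapse to one component", {
  set.seed(1)
  x <- rnorm(60)
  df <- data.frame(a = x, b = 2 * x + 5, c = rnorm(60))
  sch <- cohort_schema(feature_spec("a", "continuous"),
                       feature_spec("b", "continuous"),
                       feature_spec("c", "continuous"))
  co <- pp_cohort(df, sch)
  m <- fit_preprocess(co)
  expect_length(m$correlation_groups, 1)
  g <- m$correlation_groups[[1]]
  expect_setequal(g$members, c("a", "b"))
  expect_equal(g$eigenvalues, c(2, 0), tolerance = 1e-12)
  expect_length(g$components, 1)
  ## component scores proportional to the standardized feature sum
  X <- predict(m, co)
  comp <- X[, g$components]
  expect_equal(abs(stats::cor(comp, df$a + df$b)), 1, tolerance = 1e-12)
})

test_that("the published correlation blocks are recovered on synthetic data", {
  co <- generate_cohort(default_cohort_spec(n_subjects = 2000), seed = 77)
  m <- fit_preprocess(co)
  expect_identical(m$dropped_features$feature, "DIGIT")
  groups <- lapply(m$correlation_groups, `[[`, "members")
  expect_true(any(vapply(groups, setequal, logical(1),
                         c("ADAS11", "ADAS13", "ADASQ4"))))
  expect_true(any(vapply(groups, setequal, logical(1),
                         c("RAVLT_F", "RAVLT_PF"))))
  expect_length(groups, 2)
  ## only the first component of each group passes the Kaiser rule
  for (g in m$correlation_groups) expect_length(g$components, 1)
  ## resulting design has the expected 17 columns
  X <- predict(m, co)
  expect_identical(ncol(X), 17L)
  info <- attr(X, "column_info")
  expect_identical(sum(info$type == "indicator"), 6L)  # sex, subtype, 4 marital
})

test_that("uncorrelated features are left ungrouped", {
  set.seed(2)
  df <- as.data.frame(matrix(rnorm(300), 100, 3))
  names(df) <- c("u", "v", "w")
  sch <- cohort_schema(feature_spec("u", "continuous"),
                       feature_spec("v", "continuous"),
                       feature_spec("w", "continuous"))
  m <- fit_preprocess(pp_cohort(df, sch))
  expect_length(m$correlation_groups, 0)
})

test_that("training transform standardizes to mean 0, sd 1", {
  co <- generate_cohort(default_cohort_spec(n_subjects = 400), seed = 5)
  m <- fit_preprocess(co)
  X <- predict(m, co)
  info <- attr(X, "column_info")
  contcols <- info$name[info$type == "continuous"]
  plain <- setdiff(contcols, unlist(lapply(m$correlation_groups, `[[`, "components")))
  expect_equal(unname(colMeans(X[, plain])), rep(0, length(plain)),
               tolerance = 1e-8)
  expect_equal(unname(apply(X[, plain], 2, stats::sd)), rep(1, length(plain)),
               tolerance = 1e-8)
  ## component scores uncorrelated within a group on training data
  for (g in m$correlation_groups) {
    if (length(g$components) > 1) {
      cc <- stats::cor(X[, g$components])
      expect_lt(max(abs(cc[upper.tri(cc)])), 1e-8)
    }
  }
})

test_that("one-hot encoding matches the declared level order", {
  df <- data.frame(m = c("Married", "Never_married", "Divorced", "Widowed",
                         "Married", "Married"),
                   x = rnorm(6), stringsAsFactors = FALSE)
  sch <- cohort_schema(
    feature_spec("x", "continuous"),
    feature_spec("m", "polytomous",
                 levels = c("Never_married", "Married", "Divorced", "Widowed")))
  co <- pp_cohort(df, sch)
  m <- fit_preprocess(co)
  X <- predict(m, co)
  expect_identical(unname(X[1, c("m_Never_married", "m_Married", "m_Divorced",
                                 "m_Widowed")]), c(0, 1, 0, 0))
  ## unseen level at transform time -> all-zero indicators with a warning
  df2 <- df; df2$m[1] <- "Separated"
  co2 <- cohort_table(sprintf("t%d", 1:6), rep("A", 6), rep(c(1, 0), 3),
                      df2, cohort_schema(
                        feature_spec("x", "continuous"),
                        feature_spec("m", "polytomous",
                                     levels = c("Never_married", "Married",
                                                "Divorced", "Widowed",
                                                "Separated"))))
  expect_warning(X2 <- predict(m, co2), "unseen")
  expect_identical(unname(X2[1, c("m_Never_married", "m_Married", "m_Divorced",
                                  "m_Widowed")]), c(0, 0, 0, 0))
})

test_that("test rows are imputed and scaled with training statistics only", {
  train <- data.frame(x = c(1, 2, 3, 4, 10), s = c("a", "a", "b", "a", "b"),
                      stringsAsFactors = FALSE)
  sch <- cohort_schema(feature_spec("x", "continuous"),
                       feature_spec("s", "dichotomous", levels = c("a", "b")))
  co_tr <- pp_cohort(train, sch)
  m <- fit_preprocess(co_tr)
  ## hand computation: median 3, mean 4, sd sqrt(12.5)
  expect_equal(m$impute_values$x, 3)
  expect_equal(unname(m$standardize_params$x), c(4, sqrt(12.5)))
  expect_identical(m$impute_values$s, "a")  # mode, ties broken by level order
  test <- data.frame(x = c(NA, 6), s = c("b", NA), stringsAsFactors = FALSE)
  co_te <- pp_cohort(test, sch)
  Xte <- predict(m, co_te)
  expect_equal(unname(Xte[, "x"]), c((3 - 4) / sqrt(12.5), (6 - 4) / sqrt(12.5)))
  expect_equal(unname(Xte[, "s"]), c(1, 0))  # NA -> mode "a" -> indicator 0
  ## no leakage: refitting on the held-out table yields different parameters
  test_full <- data.frame(x = c(5, 6, 7, 8), s = c("b", "b", "a", "b"),
                          stringsAsFactors = FALSE)
  m2 <- fit_preprocess(pp_cohort(test_full, sch))
  expect_false(isTRUE(all.equal(m$standardize_params$x,
                                m2$standardize_params$x)))
})

test_that("zero-variance training features are refused by name", {
  df <- data.frame(flat = rep(2, 30), ok = rnorm(30))
  sch <- cohort_schema(feature_spec("flat", "continuous"),
                       feature_spec("ok", "continuous"))
  expect_error(fit_preprocess(pp_cohort(df, sch)), "flat")
})
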