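## cohort with controllable site sizes: site i gets sizes[i] cases with
## pos[i] converters
site_cohort <- function(sizes, pos, site_names = NULL) {
  stopifnot(length(sizes) == length(pos), all(pos <= sizes))
  site_names <- site_names %||% sprintf("S%02d", seq_along(sizes))
  site <- rep(site_names, sizes)
  y <- unlist(mapply(function(n, k) c(rep(1, k), rep(0, n - k)),
                     sizes, pos, SIMPLIFY = FALSE))
  n <- length(site)
  cohort_table(sprintf("s%04d", seq_len(n)), site, y,
               data.frame(x = seq_len(n) / n),
               cohort_schema(feature_spec("x", "continuous")))
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("five equal sites admit the singleton partition", {
  co <- site_cohort(sizes = rep(20, 5), pos = rep(7, 5))
  cons <- split_constraints(n_candidates = 200)
  cand <- generate_candidates(co, cons, seed = 1)
  ## every candidate is a single site at exactly 20% of cases
  expect_true(all(vapply(cand, function(s) length(s$sites) == 1, logical(1))))
  expect_true(all(vapply(cand, `[[`, numeric(1), "n_cases") == 20))
  ret <- retain_by_prevalence(cand, cons, co)
  plan <- find_partition(ret, co, cons)
  expect_s3_class(plan, "split_plan")
  expect_true(validate_split(plan, co, cons))
  expect_identical(sort(unique(plan$counts$n)), 20L)
})

test_that("a site exceeding the size band never enters a candidate", {
  co <- site_cohort(sizes = c(30, 14, 14, 14, 14, 14), pos = c(10, 5, 5, 5, 5, 5))
  cand <- generate_candidates(co, split_constraints(n_candidates = 500), seed = 3)
  has_big <- vapply(cand, function(s) "S01" %in% s$sites, logical(1))
  expect_false(any(has_big))
})

test_that("all candidates satisfy the size band on a 58-site cohort", {
  co <- generate_cohort(default_cohort_spec(), seed = 21)
  cons <- split_constraints(n_candidates = 2000)
  cand <- generate_candidates(co, cons, seed = 9)
  frac <- vapply(cand, `[[`, numeric(1), "n_cases") / nrow(co)
  expect_true(all(frac >= 0.19 & frac <= 0.21))
  ## deterministic given the seed; site sets deduplicated
  cand2 <- generate_candidates(co, cons, seed = 9)
  expect_identical(cand, cand2)
  keys <- vapply(cand, function(s) paste(s$sites, collapse = "|"), character(1))
  expect_false(anyDuplicated(keys) > 0)
})

test_that("prevalence retention applies the band and reports the rate", {
  cons <- split_constraints(prev_lo = 0.3552, prev_hi = 0.3612)
  co <- site_cohort(sizes = c(115, 100), pos = c(41, 36))
  cand <- list(list(sites = "S01", n_cases = 115, n_pos = 41),   # 35.65% in
               list(sites = "S02", n_cases = 100, n_pos = 30))   # 30% out
  attr(cand, "n_generated") <- 10
  ret <- retain_by_prevalence(cand, cons, co)
  expect_length(ret, 1)
  expect_identical(ret[[1]]$sites, "S01")
  expect_equal(attr(ret, "retention_rate"), 1 / 10)
  ## an empty retention is a reported outcome, not an error
  none <- retain_by_prevalence(cand[2], cons, co)
  expect_length(none, 0)
})

test_that("retention-rate arithmetic matches the published bookkeeping", {
  expect_equal(round(100 * retention_rate(567, 10000), 2), 5.67)
  expect_error(retention_rate(11, 10))
})

test_that("partition search equals exhaustive combination enumeration", {
  set.seed(42)
  n_found <- 0L
  for (trial in 1:4) {
    sizes <- sample(8:12, 12, replace = TRUE)
    pos <- rbinom(12, sizes, 0.36)
    if (any(pos == 0) || any(pos == sizes)) next
    co <- site_cohort(sizes, pos)
    cons <- split_constraints(size_lo = 0.10, size_hi = 0.40,
                              prev_lo = 0.05, prev_hi = 0.95,
                              n_candidates = 60)
    cand <- generate_candidates(co, cons, seed = trial)
    ret <- retain_by_prevalence(cand, cons, co)
    ret <- ret[seq_len(min(length(ret), 25))]   # keep C(m,5) tractable
    if (trial == 1) {
      ## plant a known tiling so both search and oracle exercise the
      ## partition-exists branch at least once
      groups <- list(1:3, 4:6, 7:8, 9:10, 11:12)
      planted <- lapply(groups, function(g) {
        list(sites = sprintf("S%02d", g), n_cases = sum(sizes[g]),
             n_pos = sum(pos[g]))
      })
      ret <- c(ret, planted)
    }
    res <- find_partition(ret, co, cons)
    ## independent oracle: enumerate every 5-combination of retained subsets
    all_sites <- sort(unique(co$site_id))
    found_any <- FALSE
    if (length(ret) >= 5) {
      combs <- utils::combn(length(ret), 5)
      for (ci in seq_len(ncol(combs))) {
        ss <- unlist(lapply(ret[combs[, ci]], `[[`, "sites"))
        if (!anyDuplicated(ss) && setequal(ss, all_sites)) {
          found_any <- TRUE
          break
        }
      }
    }
    expect_identical(inherits(res, "split_plan"), found_any)
    if (found_any) {
      n_found <- n_found + 1L
      expect_true(validate_split(res, co, cons))
    }
  }
  ## at least one trial must exercise the "partition exists" branch
  expect_gte(n_found, 1L)
})

test_that("overlapping candidates that cannot tile yield not-found", {
  co <- site_cohort(sizes = rep(10, 5), pos = rep(4, 5))
  cons <- split_constraints(size_lo = 0.19, size_hi = 0.41,
                            prev_lo = 0.01, prev_hi = 0.99, n_candidates = 10)
  ## hand-built candidates: every pair shares site S01
  cand <- list(list(sites = c("S01", "S02"), n_cases = 20, n_pos = 8),
               list(sites = c("S01", "S03"), n_cases = 20, n_pos = 8),
               list(sites = c("S01", "S04"), n_cases = 20, n_pos = 8))
  res <- find_partition(cand, co, cons)
  expect_s3_class(res, "split_failure")
  expect_identical(res$status, "not_found")
  expect_lt(res$best_coverage, 1)
})

test_that("the validator enforces partition, bands and feasibility", {
  co <- site_cohort(sizes = rep(20, 5), pos = rep(7, 5))
  cons <- split_constraints()
  good <- stats::setNames(1:5, sprintf("S%02d", 1:5))
  plan <- split_plan(good, co, cons)
  expect_true(validate_split(plan, co, cons))
  ## duplicated subset -> a subset empty and sizes off
  bad <- plan
  bad$assignment[] <- c(1L, 1L, 2L, 3L, 4L)
  v <- validate_split(bad, co, cons)
  expect_false(isTRUE(v))
  ## infeasible constraint set rejected outright
  expect_error(split_constraints(k = 5, size_lo = 0.25, size_hi = 0.30),
               "infeasible")
  ## prevalence band violation detected
  lop <- site_cohort(sizes = rep(20, 5), pos = c(2, 7, 7, 7, 12))
  v2 <- validate_split(plan, lop, cons)
  expect_false(isTRUE(v2))
})

test_that("the full split search is deterministic and self-validating", {
  co <- protocol_cohort()
  cons <- split_constraints(n_candidates = 10000)
  a <- search_split(co, cons, seed = 11)
  b <- search_split(co, cons, seed = 11)
  expect_s3_class(a, "split_plan")
  expect_identical(a$assignment, b$assignment)
  expect_true(validate_split(a, co, cons))
  expect_true(attr(a, "retention_rate") > 0 && attr(a, "retention_rate") < 1)
  ## each subject lands in exactly one subset
  sub <- subset_of(a, co)
  expect_false(anyNA(sub))
  expect_identical(sum(a$counts$n), nrow(co))
})
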