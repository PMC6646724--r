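## Shared fixtures, built in code at load time.

tiny_schema <- function() {
  cohort_schema(
    feature_spec("score", "continuous"),
    feature_spec("grade", "continuous"),
    feature_spec("sex", "dichotomous", levels = c("Male", "Female")),
    feature_spec("marital", "polytomous",
                 levels = c("Never_married", "Married", "Divorced", "Widowed"))
  )
}

tiny_cohort <- function() {
  cohort_table(
    subject_id = sprintf("s%02d", 1:8),
    site_id = c("A", "A", "B", "B", "C", "C", "D", "D"),
    outcome = c(1, 0, 1, 0, 0, 1, 0, 0),
    features = data.frame(
      score = c(1.5, 2.5, 3.5, NA, 5.5, 6.5, 7.5, 8.5),
      grade = c(10, 12, 14, 16, 18, 20, 22, 24),
      sex = c("Male", "Female", "Male", "Male", "Female", "Male", "Female", "Male"),
      marital = c("Married", "Married", "Divorced", "Widowed", "Married",
                  "Never_married", "Married", NA),
      stringsAsFactors = FALSE
    ),
    schema = tiny_schema()
  )
}

## design matrix with column_info attribute, one informative continuous
## column, optional noise columns and an indicator
toy_design <- function(n = 200, p_noise = 3, seed = 1, signal = 1.5) {
  set.seed(seed)
  y <- rep(c(0L, 1L), length.out = n)
  X <- cbind(signalcol = rnorm(n, mean = signal * y),
             matrix(rnorm(n * p_noise), n,
                    dimnames = list(NULL, paste0("noise", seq_len(p_noise)))),
             flag = rbinom(n, 1, 0.3 + 0.3 * y))
  attr(X, "column_info") <- data.frame(
    name = colnames(X),
    type = c(rep("continuous", 1 + p_noise), "indicator"),
    stringsAsFactors = FALSE
  )
  list(X = X, y = y)
}

## mid-point configuration of a search space
config_mid <- function(space) {
  if (!length(space)) return(list())
  out <- lapply(space, function(d) {
    v <- if (d$scale == "log") exp((log(d$lo) + log(d$hi)) / 2)
         else (d$lo + d$hi) / 2
    if (d$type == "integer") as.integer(round(v)) else v
  })
  out
}

with_test_seed <- function(seed, expr) {
  set.seed(seed)
  expr
}

## all-pairs brute-force AUROC oracle (independent of the rank formula)
auroc_pairs <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) tot <- tot + sum(p > neg) + 0.5 * sum(p == neg)
  tot / (length(pos) * length(neg))
}

## a 550-subject cohort on 25 sites: enough cases per site that the
## site-tiling partition search succeeds quickly, used by protocol-level tests
protocol_cohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- generate_cohort(default_cohort_spec(n_sites = 25), seed = 2024)
    }
    cache
  }
})

protocol_plan <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- search_split(protocol_cohort(),
                             split_constraints(n_candidates = 10000), seed = 11)
      stopifnot(inherits(cache, "split_plan"))
    }
    cache
  }
})
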