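#' Constraints for the site-independent stratified partition
#'
#' The cohort is divided into `k` mutually exclusive subsets at the level of
#' recruitment sites: all subjects of a site land in the same subset. Each
#' subset must contain a fraction of the cohort inside `[size_lo, size_hi]`
#' and a converter proportion inside `[prev_lo, prev_hi]`.
#'
#' @param k Number of subsets (default 5).
#' @param size_lo,size_hi Case-fraction band per subset (defaults 0.19, 0.21).
#' @param prev_lo,prev_hi Converter-proportion band; if `NULL`, computed from
#'   the cohort at search time as overall prevalence +/- `prev_margin`.
#' @param prev_margin Half-width of the default prevalence band, in absolute
#'   proportion (default 0.003, i.e. +/- 0.30 percentage points).
#' @param n_candidates Random candidate subsets to generate (default 10000).
#' @param max_combinations Node budget of the exact-cover search (default 1e7).
#' @return Object of class `split_constraints`.
#' @export
split_constraints <- function(k = 5, size_lo = 0.19, size_hi = 0.21,
                              prev_lo = NULL, prev_hi = NULL,
                              prev_margin = 0.003,
                              n_candidates = 10000, max_combinations = 1e7) {
  stopifnot(k >= 2, size_lo > 0, size_lo < size_hi, size_hi < 1,
            n_candidates >= 1, max_combinations >= 1)
  if (!(k * size_lo <= 1 && 1 <= k * size_hi))
    stop("infeasible size band: need k*size_lo <= 1 <= k*size_hi")
  if (!is.null(prev_lo) && !is.null(prev_hi)) stopifnot(prev_lo < prev_hi)
  structure(list(k = k, size_lo = size_lo, size_hi = size_hi,
                 prev_lo = prev_lo, prev_hi = prev_hi,
                 prev_margin = prev_margin, n_candidates = n_candidates,
                 max_combinations = max_combinations),
            class = "split_constraints")
}

prevalence_band <- function(constraints, table) {
  if (!is.null(constraints$prev_lo) && !is.null(constraints$prev_hi))
    return(c(constraints$prev_lo, constraints$prev_hi))
  p <- class_prevalence(table)
  c(p - constraints$prev_margin, p + constraints$prev_margin)
}

site_counts <- function(table) {
  n <- tapply(rep(1L, nrow(table)), table$site_id, sum)
  pos <- tapply(table$outcome, table$site_id, sum)
  data.frame(site = names(n), n = as.integer(n), n_pos = as.integer(pos),
             stringsAsFactors = FALSE)
}

#' Generate candidate site subsets within the size band
#'
#' Repeatedly grows a subset by adding all subjects from a randomly chosen
#' recruitment site (drawn uniformly without replacement) until the included
#' case fraction enters `[size_lo, size_hi]` (success) or overshoots
#' `size_hi` (the candidate is abandoned; it still counts against
#' `n_candidates`). Identical site sets are deduplicated.
#'
#' @param table A `cohort_table`.
#' @param constraints A `split_constraints`.
#' @param seed Integer seed.
#' @return List of candidates, each `list(sites, n_cases, n_pos)`, with
#'   attributes `n_generated` (attempts) and `n_kept`.
#' @export
generate_candidates <- function(table, constraints, seed) {
  sc <- site_counts(table)
  n_total <- nrow(table)
  if (nrow(sc) < constraints$k)
    stop("fewer sites than subsets requested")
  if (all(sc$n / n_total > constraints$size_hi))
    stop("every site alone exceeds the size band; no candidate can start")
  lo <- constraints$size_lo * n_total
  hi <- constraints$size_hi * n_total
  cand <- with_seed(seed, {
    out <- vector("list", constraints$n_candidates)
    kept <- 0L
    for (i in seq_len(constraints$n_candidates)) {
      ord <- sample.int(nrow(sc))
      tot <- 0L
      pos <- 0L
      taken <- integer(0)
      for (j in ord) {
        tot <- tot + sc$n[j]
        pos <- pos + sc$n_pos[j]
        taken <- c(taken, j)
        if (tot >= lo && tot <= hi) {
          kept <- kept + 1L
          out[[kept]] <- list(sites = sort(sc$site[taken]),
                              n_cases = tot, n_pos = pos)
          break
        }
        if (tot > hi) break
      }
    }
    attr(out, "n_kept") <- kept
    out
  })
  kept <- attr(cand, "n_kept")
  cand <- cand[seq_len(kept)]
  key <- vapply(cand, function(s) paste(s$sites, collapse = "|"), character(1))
  cand <- cand[!duplicated(key)]
  attr(cand, "n_generated") <- constraints$n_candidates
  attr(cand, "n_kept") <- kept
  cand
}

#' Retain candidates inside the prevalence band
#'
#' @param candidates Output of [generate_candidates()].
#' @param constraints A `split_constraints`.
#' @param table Cohort the candidates came from (used when the band must be
#'   recomputed from overall prevalence).
#' @return Filtered candidate list; attribute `retention_rate` reports the
#'   retained fraction of all generated attempts (an empty result is a valid
#'   outcome, not an error).
#' @export
retain_by_prevalence <- function(candidates, constraints, table) {
  band <- prevalence_band(constraints, table)
  keep <- vapply(candidates, function(s) {
    pr <- s$n_pos / s$n_cases
    pr >= band[1] && pr <= band[2]
  }, logical(1))
  out <- candidates[keep]
  n_gen <- attr(candidates, "n_generated") %||% length(candidates)
  attr(out, "retention_rate") <- retention_rate(length(out), n_gen)
  attr(out, "n_generated") <- n_gen
  out
}

#' Candidate retention rate
#'
#' Bookkeeping helper: the fraction of generated candidate subsets that
#' satisfied the prevalence band.
#'
#' @param n_retained,n_generated Counts.
#' @return `n_retained / n_generated`.
#' @export
retention_rate <- function(n_retained, n_generated) {
  stopifnot(n_generated > 0, n_retained >= 0, n_retained <= n_generated)
  n_retained / n_generated
}

#' Search for an exact k-subset partition of the sites
#'
#' Depth-first exact-cover search over the retained candidates: candidates are
#' encoded as site index sets; at each node the branch covers the
#' smallest-indexed uncovered site, with disjointness pruning. Equivalent to
#' exhaustively enumerating all k-combinations of candidates, but tractable.
#' The first partition in this deterministic order is returned.
#'
#' @param retained Candidate list from [retain_by_prevalence()].
#' @param table The cohort.
#' @param constraints A `split_constraints`.
#' @return A `split_plan` on success; otherwise a `split_failure` with
#'   `status` `"not_found"` (search exhausted) or `"budget_exhausted"`, and
#'   `best_coverage` diagnostics.
#' @export
find_partition <- function(retained, table, constraints) {
  if (!length(retained)) {
    return(structure(list(status = "not_found", best_coverage = 0,
                          n_candidates = 0), class = "split_failure"))
  }
  sites <- sort(unique(table$site_id))
  m <- length(sites)
  k <- constraints$k
  n_total <- nrow(table)
  sets <- lapply(retained, function(s) match(s$sites, sites))
  sizes <- vapply(retained, `[[`, numeric(1), "n_cases")
  lo_cases <- constraints$size_lo * n_total
  hi_cases <- constraints$size_hi * n_total
  ## bitmask encoding: sites packed 31 per integer word
  nw <- (m + 30) %/% 31
  pack <- function(idx) {
    wmask <- integer(nw)
    for (s in idx) {
      w <- (s - 1) %/% 31 + 1
      wmask[w] <- bitwOr(wmask[w], bitwShiftL(1L, (s - 1) %% 31))
    }
    wmask
  }
  masks <- lapply(sets, pack)
  full <- pack(seq_len(m))
  by_site <- vector("list", m)
  for (i in seq_along(sets)) for (s in sets[[i]]) by_site[[s]] <- c(by_site[[s]], i)
  covered <- integer(nw)
  covered_sites <- logical(m)
  covered_cases <- 0
  chosen <- integer(0)
  best_cov <- 0L
  nodes <- 0L
  budget <- constraints$max_combinations
  result <- NULL
  recurse <- function(depth) {
    if (!is.null(result) || nodes > budget) return()
    nodes <<- nodes + 1L
    ncov <- sum(covered_sites)
    best_cov <<- max(best_cov, ncov)
    if (ncov == m) {
      if (depth == k && abs(covered_cases - n_total) < 0.5) result <<- chosen
      return()
    }
    if (depth >= k) return()
    ## case-count pruning: the remaining subsets must be able to absorb
    ## exactly the uncovered cases within the size band
    left <- k - depth
    remaining <- n_total - covered_cases
    if (remaining < left * lo_cases - 1e-9 || remaining > left * hi_cases + 1e-9)
      return()
    target <- which.min(covered_sites)  # smallest-indexed uncovered site
    for (i in by_site[[target]]) {
      mk <- masks[[i]]
      if (any(bitwAnd(covered, mk) != 0L)) next
      covered <<- bitwOr(covered, mk)
      covered_sites[sets[[i]]] <<- TRUE
      covered_cases <<- covered_cases + sizes[i]
      chosen <<- c(chosen, i)
      recurse(depth + 1)
      covered <<- bitwAnd(covered, bitwNot(mk))
      covered_sites[sets[[i]]] <<- FALSE
      covered_cases <<- covered_cases - sizes[i]
      chosen <<- chosen[-length(chosen)]
      if (!is.null(result)) return()
    }
  }
  recurse(0)
  if (is.null(result)) {
    status <- if (nodes > budget) "budget_exhausted" else "not_found"
    return(structure(list(status = status, best_coverage = best_cov / m,
                          nodes = nodes, n_candidates = length(retained)),
                     class = "split_failure"))
  }
  assignment <- integer(m)
  for (j in seq_along(result)) assignment[sets[[result[j]]]] <- j
  names(assignment) <- sites
  split_plan(assignment, table, constraints)
}

#' Construct and validate a split plan
#'
#' @param assignment Named integer vector: site id -> subset index 1..k.
#' @param table The cohort.
#' @param constraints A `split_constraints`.
#' @return Object of class `split_plan` with per-subset case and converter
#'   counts; errors if the assignment violates any constraint.
#' @export
split_plan <- function(assignment, table, constraints) {
  plan <- structure(list(assignment = assignment, k = constraints$k,
                         constraints = constraints),
                    class = "split_plan")
  counts <- plan_counts(plan, table)
  plan$counts <- counts
  ok <- validate_split(plan, table, constraints)
  if (!isTRUE(ok)) stop("invalid split plan: ", attr(ok, "reason"))
  plan
}

plan_counts <- function(plan, table) {
  sub <- subset_of(plan, table)
  n <- tapply(rep(1L, nrow(table)), sub, sum)
  pos <- tapply(table$outcome, sub, sum)
  data.frame(subset = as.integer(names(n)), n = as.integer(n),
             n_pos = as.integer(pos),
             prevalence = as.integer(pos) / as.integer(n))
}

#' Subset index of each subject under a plan
#' @param plan A `split_plan`.
#' @param table A `cohort_table`.
#' @return Integer vector in 1..k (NA for sites absent from the plan).
#' @export
subset_of <- function(plan, table) {
  unname(plan$assignment[table$site_id])
}

#' Independently validate a split plan
#'
#' Checks that every site is assigned exactly once to one of 1..k, the
#' subsets are jointly exhaustive over the cohort's sites, and each subset
#' satisfies the size and prevalence bands.
#'
#' @param plan A `split_plan`.
#' @param table The cohort.
#' @param constraints A `split_constraints`.
#' @return `TRUE`, or `FALSE` with attribute `"reason"`.
#' @export
validate_split <- function(plan, table, constraints) {
  fail <- function(msg) structure(FALSE, reason = msg)
  if (!(constraints$k * constraints$size_lo <= 1 &&
        1 <= constraints$k * constraints$size_hi))
    return(fail("infeasible size band"))
  sites <- unique(table$site_id)
  a <- plan$assignment
  if (!all(sites %in% names(a))) return(fail("unassigned site(s)"))
  if (anyDuplicated(names(a))) return(fail("site assigned more than once"))
  if (!all(a[sites] %in% seq_len(constraints$k))) return(fail("subset index out of range"))
  if (length(unique(a[sites])) != constraints$k) return(fail("empty subset"))
  sub <- a[table$site_id]
  n_total <- nrow(table)
  band <- prevalence_band(constraints, table)
  for (j in seq_len(constraints$k)) {
    nj <- sum(sub == j)
    frac <- nj / n_total
    if (frac < constraints$size_lo - 1e-12 || frac > constraints$size_hi + 1e-12)
      return(fail(sprintf("subset %d size fraction %.4f outside band", j, frac)))
    pj <- sum(table$outcome[sub == j]) / nj
    if (pj < band[1] - 1e-12 || pj > band[2] + 1e-12)
      return(fail(sprintf("subset %d prevalence %.4f outside band", j, pj)))
  }
  TRUE
}

#' One-call site-independent partition search
#'
#' Candidate generation, prevalence retention and exact-cover search in one
#' step; deterministic given `seed`.
#'
#' @inheritParams generate_candidates
#' @return A `split_plan` or `split_failure`; the retention rate of the
#'   candidate stage is attached as attribute `"retention_rate"`.
#' @export
search_split <- function(table, constraints = split_constraints(), seed = 1) {
  cand <- generate_candidates(table, constraints, seed)
  ret <- retain_by_prevalence(cand, constraints, table)
  res <- find_partition(ret, table, constraints)
  attr(res, "retention_rate") <- attr(ret, "retention_rate")
  res
}

#' @export
print.split_plan <- function(x, ...) {
  cat(sprintf("Site-independent split: %d subsets over %d sites\n",
              x$k, length(x$assignment)))
  print(x$counts, row.names = FALSE)
  invisible(x)
}

#' @export
print.split_failure <- function(x, ...) {
  cat(sprintf("No partition found (%s); best site coverage %.1f%%\n",
              x$status, 100 * x$best_coverage))
  invisible(x)
}
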