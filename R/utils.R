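`%||%` <- function(a, b) if (is.null(a)) b else a

## Derive a stage seed from a master seed via a counter, keeping the result a
## valid 32-bit integer. Stages of the protocol get independent, reproducible
## streams without consuming each other's RNG state.
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  offsets <- c(
    generate = 104729L, split = 130363L, preprocess = 15485863L,
    select = 49979687L, zoo = 67867967L, ensemble = 86028121L,
    threshold = 7368787L, bootstrap = 27644437L, importance = 957689077L,
    cv = 2038074743L, search = 179424673L
  )
  off <- if (stage %in% names(offsets)) offsets[[stage]] else sum(utf8ToInt(stage))
  as.integer((as.numeric(seed) * 48271 + off) %% 2147483647)
}

## Evaluate an expression under a local RNG state: seeds deterministically and
## restores the caller's .Random.seed afterwards.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  }, add = TRUE)
  set.seed(seed)
  expr
}

## Stratified fold assignment: within each class, subjects are shuffled and
## dealt round-robin into folds, so fold class proportions track the sample's.
stratified_folds <- function(y, k) {
  fold <- integer(length(y))
  for (cls in unique(y)) {
    idx <- which(y == cls)
    idx <- idx[sample.int(length(idx))]
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}
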