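## Seed plumbing: one root seed, one named substream per stochastic stage.
## Substream seeds are a deterministic function of (root, stage label) kept
## below 2^31 so they remain valid R integer seeds.
stage_seed <- function(seed, stage) {
  if (is.null(seed)) return(NULL)
  stopifnot(is.character(stage), length(stage) == 1L)
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) + 10007 * h) %% 2147483629)
}

## Evaluate `expr` under `seed` without disturbing the caller's RNG state;
## with seed = NULL the global stream is used as-is (tidyverse convention).
with_stage_seed <- function(seed, expr) {
  if (is.null(seed)) expr else withr::with_seed(seed, expr)
}

## Uniformly pick one row index per group, vectorized: attach a random key,
## order by (group, key), keep the first row of each group.
pick_one_per_group <- function(group) {
  if (length(group) == 0L) return(integer(0))
  key <- runif(length(group))
  o <- order(group, key)
  o[!duplicated(group[o])]
}

`%||%` <- function(x, y) if (is.null(x)) y else x
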