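# Internal helpers shared across modules.

# Evaluate expr with a temporary RNG state seeded by `seed`, restoring the
# caller's RNG afterwards so package functions never disturb user randomness.
with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

clamp <- function(p, lo, hi) pmin(pmax(p, lo), hi)

`%||%` <- function(a, b) if (is.null(a)) b else a

# Stratified fold assignment: a seeded random partition into k folds,
# performed separately within each stratum so every training split retains
# treated, internal-control, and external-control units.
stratified_folds <- function(strata, k, seed) {
  n <- length(strata)
  if (k <= 1L) return(rep(0L, n))
  fold <- integer(n)
  with_local_seed(seed, {
    for (s in unique(strata)) {
      idx <- which(strata == s)
      fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
    }
  })
  fold
}
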