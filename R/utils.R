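# Internal helpers shared across modules.

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's RNG afterwards so library code never perturbs user-level randomness.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("`seed` must be a single finite number", call. = FALSE)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv(), inherits = FALSE) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Add a length-ncol(M) vector to every row of M (column-wise recycling).
addrow <- function(M, b) M + rep(b, each = nrow(M))

# Row-wise softmax of a matrix, numerically stabilised.
softmax_rows <- function(S) {
  mx <- S[, 1]
  for (cc in seq_len(ncol(S))[-1]) mx <- pmax(mx, S[, cc])
  E <- exp(S - mx)
  E / rowSums(E)
}

is_binary <- function(x) all(x == 0 | x == 1)

`%||%` <- function(a, b) if (is.null(a)) b else a
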