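# Internal helpers shared across modules.

# Stable descending order: score descending, then identifier ascending.
# method = "radix" is locale-independent and stable, so equal scores are
# always broken the same way on every platform.
stable_order <- function(scores, ids) {
  order(-scores, ids, method = "radix")
}

# Evaluate `code` with the RNG seeded at `seed`, restoring the caller's RNG
# state afterwards so generators are pure functions of their arguments.
with_seed <- function(seed, code) {
  if (is.null(seed)) {
    return(force(code))
  }
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Deterministic child seed for stage `k` of a run seeded with `seed`;
# kept below 2^31 so it is always a valid integer seed.
derive_seed <- function(seed, k) {
  (abs(as.numeric(seed)) %% 2097143) * 1000 + (k %% 1000)
}

check_finite_matrix <- function(x, what = "matrix") {
  if (!is.matrix(x) || !is.numeric(x)) {
    stop(what, " must be a numeric matrix", call. = FALSE)
  }
  if (any(!is.finite(x))) {
    stop(what, " contains non-finite values", call. = FALSE)
  }
  invisible(x)
}
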