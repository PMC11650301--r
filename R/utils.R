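# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

logsumexp <- function(x) {
  x <- x[is.finite(x) | x == -Inf]
  if (length(x) == 0L) return(-Inf)
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# log(exp(la) - exp(lb)) for la >= lb; returns -Inf when the difference
# underflows (or la == lb), which is the structural-zero case.
logdiffexp <- function(la, lb) {
  if (lb >= la) return(-Inf)
  la + log1p(-exp(lb - la))
}

stop_if_not_scalar_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < 0 || x > 1) {
    stop(sprintf("`%s` must be a single probability in [0, 1]", name),
         call. = FALSE)
  }
  invisible(x)
}

# Column-standardize, leaving zero-variance columns at 0 instead of NaN.
scale_safe <- function(m) {
  m <- sweep(m, 2L, colMeans(m), "-")
  sds <- sqrt(colSums(m^2) / max(1, nrow(m) - 1))
  ok <- sds > 0
  m[, ok] <- sweep(m[, ok, drop = FALSE], 2L, sds[ok], "/")
  m
}

# Derive a stream-specific 32-bit seed from a base seed.
derive_seed <- function(seed, offset) {
  (as.integer(seed) + as.integer(offset) * 1000003L) %% 2147483647L
}
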