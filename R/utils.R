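# Internal helpers shared across modules. All randomness in the package is
# funnelled through with_preserved_seed() so no function leaves the global
# RNG state altered, and through derive_seed() so variant/element sub-seeds
# are a pure function of (master seed, counter) -- adding variants never
# changes earlier ones.

with_preserved_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      stats::runif(1)  # force RNG initialisation so state can be captured
    }
    old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    set.seed(as.integer(seed))
  }
  expr
}

# Counter-based sub-seed derivation, kept below 2^31. Multipliers are
# classic Lehmer/MINSTD constants; products stay < 2^53 so the double
# arithmetic is exact.
derive_seed <- function(seed, index, stream = 0L) {
  s <- as.numeric(seed) %% 2147483647
  v <- (s * 48271 + as.numeric(index) * 16807 + as.numeric(stream) * 69621 + 1) %% 2147483647
  as.integer(v)
}

# Row-wise log-sum-exp of a matrix, numerically stable.
row_logsumexp <- function(m) {
  mx <- m[, 1L]
  if (ncol(m) > 1L) {
    for (k in 2L:ncol(m)) mx <- pmax(mx, m[, k])
  }
  mx + log(rowSums(exp(m - mx)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_gmmaug <- function(...) stop(sprintf(...), call. = FALSE)
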