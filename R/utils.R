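# Internal helpers shared across modules.

# Evaluate `expr` under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is restored afterwards. seed = NULL uses the current stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("`seed` must be a single integer", call. = FALSE)
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

# Derive a reproducible child seed from a master seed, kept inside the 32-bit
# integer range.
derive_seed <- function(seed, index) {
  if (is.null(seed)) return(NULL)
  as.integer((as.double(seed) + 104729 * as.double(index)) %% .Machine$integer.max)
}

logistic <- function(eta) 1 / (1 + exp(-eta))

# Bernoulli log-likelihood with probability clipping for numerical safety.
bernoulli_loglik <- function(y, p, w = NULL, eps = 1e-12) {
  p <- pmin(pmax(p, eps), 1 - eps)
  ll <- y * log(p) + (1 - y) * log(1 - p)
  if (!is.null(w)) ll <- w * ll
  sum(ll)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

is_binary01 <- function(x) {
  x <- x[!is.na(x)]
  length(x) > 0L && all(x %in% c(0, 1))
}
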