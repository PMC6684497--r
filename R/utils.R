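# numerically stable log-sum-exp helpers used throughout the bridge code

logsumexp <- function(x) {
  x <- x[!is.na(x)]
  if (!length(x)) return(-Inf)
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# elementwise log(exp(a) + exp(b)); -Inf legal in either argument
logsumexp2 <- function(a, b) {
  m <- pmax(a, b)
  lo <- pmin(a, b)
  out <- m + log1p(exp(lo - m))
  out[!is.finite(m)] <- m[!is.finite(m)]
  out
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# multivariate log-gamma, log Gamma_P(a)
lmvgamma <- function(a, P) {
  P * (P - 1) / 4 * log(pi) + sum(lgamma(a + (1 - seq_len(P)) / 2))
}

# draw a seed vector reproducibly from a single master seed; values stay
# within the 32-bit integer range required by set.seed()
derive_seeds <- function(seed, n) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}
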