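# shared fixtures and small independent oracles used across test files

# one-tree binomial MPT: single parameter p, two categories
binomial_spec <- function() {
  parse_eqn("t hit p\nt miss (1-p)", name = "binomial")
}

pc_spec <- function() pair_clustering_fixture()$spec

# small synthetic pair-clustering dataset (two conditions)
pc_dataset <- function(I = 8, seed = 42) {
  fx <- pair_clustering_fixture()
  generate_dataset(fx$model, fx$truth, I = I, J = c(20, 10), seed = seed)
}

# generic random-walk Metropolis for low-dimensional targets; used to
# draw "posterior" samples for bridge tests independently of the
# package's latent-trait sampler
rw_metropolis <- function(log_post, init, n, scale, burn = 500,
                          thin = 1) {
  d <- length(init)
  x <- init
  lp <- log_post(matrix(x, 1))
  out <- matrix(NA_real_, n, d)
  kept <- 0
  total <- burn + n * thin
  for (t in seq_len(total)) {
    prop <- x + scale * rnorm(d)
    lp_prop <- log_post(matrix(prop, 1))
    if (is.finite(lp_prop) && log(runif(1)) < lp_prop - lp) {
      x <- prop
      lp <- lp_prop
    }
    if (t > burn) {
      kept <- kept + 1
      if (kept %% thin == 0) out[kept %/% thin, ] <- x
    }
  }
  out
}

# independent hand-written log unnormalized posterior for the
# single-parameter (P=1) latent-trait binomial toy: psi = (mu, xt,
# omega_1..omega_I); written directly from the model's density, not via
# package internals
toy_lp_by_hand <- function(psi, counts_hit, J, xi_max = 10, nu = 2) {
  I <- length(counts_hit)
  vapply(seq_len(nrow(psi)), function(j) {
    mu <- psi[j, 1]
    xt <- psi[j, 2]
    om <- psi[j, 2 + seq_len(I)]
    xi <- xi_max * pnorm(xt)
    th <- pnorm(mu + xi * om)
    ll <- sum(dbinom(counts_hit, J, th, log = TRUE))
    gf <- lgamma((nu + I) / 2) - lgamma(nu / 2) - I / 2 * log(pi) -
      (nu + I) / 2 * log(sum(om^2) + 1)
    ll + gf + dnorm(mu, log = TRUE) + dnorm(xt, log = TRUE)
  }, 0)
}
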