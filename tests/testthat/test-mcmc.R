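test_that("Q updates match the inverse-Wishart full conditional", {
  set.seed(21)
  # Omega = 0, I = 5, P = 2, nu = 3: full conditional is IW(8, I_2)
  # with mean I_2 / (8 - 2 - 1)
  draws <- replicate(2e4, update_Q(matrix(0, 5, 2), 3))
  emp <- apply(draws, c(1, 2), mean)
  expect_equal(emp, diag(2) / 5, tolerance = 0.02)
  # P = 1 reduces to inverse gamma: IW(nu + I, s) = InvGamma((nu+I)/2, s/2)
  set.seed(22)
  om <- matrix(c(0.5, -1, 2), 3, 1)
  s <- sum(om^2) + 1
  q_draws <- replicate(2e4, update_Q(om, 2)[1, 1])
  set.seed(23)
  ig <- (s / 2) / rgamma(2e4, shape = (2 + 3) / 2, rate = 1)
  expect_equal(quantile(q_draws, c(.1, .25, .5, .75, .9)),
               quantile(ig, c(.1, .25, .5, .75, .9)), tolerance = 0.05)
})

make_chains <- function(draws_list, labels = NULL) {
  n <- nrow(draws_list[[1]])
  d <- ncol(draws_list[[1]])
  arr <- array(NA_real_, c(n, d, length(draws_list)))
  for (ch in seq_along(draws_list)) arr[, , ch] <- draws_list[[ch]]
  if (is.null(labels)) labels <- paste0("dim", seq_len(d))
  dimnames(arr) <- list(NULL, labels, NULL)
  structure(list(draws = arr, labels = labels,
                 n_chains = length(draws_list), n_iter = n,
                 settings = list(), seed = NA, acceptance = NULL),
            class = "mpt_chains")
}

test_that("R-hat separates mixed from unmixed chains", {
  set.seed(24)
  good <- make_chains(list(matrix(rnorm(5000)), matrix(rnorm(5000))))
  expect_true(rhat(good) > 0.99 && rhat(good) < 1.01)
  bad <- make_chains(list(matrix(rnorm(5000, 0)), matrix(rnorm(5000, 10))))
  expect_gt(rhat(bad), 1.05)
  expect_equal(rhat_flags(bad), "dim1")
  expect_length(rhat_flags(good), 0)
  one <- make_chains(list(matrix(rnorm(100))))
  expect_error(rhat(one), "at least 2 chains")
})

test_that("effective sample size tracks autocorrelation", {
  set.seed(25)
  n <- 1e4
  iid <- make_chains(list(matrix(rnorm(n))))
  expect_equal(unname(effective_sample_size(iid)), n, tolerance = 0.15)
  # AR(1) with rho = 0.5: asymptotic ESS = n (1-rho)/(1+rho) = n/3
  ar <- as.vector(arima.sim(list(ar = 0.5), n))
  expect_equal(effective_sample_size(matrix(ar)), n / 3, tolerance = 0.2)
  # thinning raises the ESS fraction
  thick <- as.vector(arima.sim(list(ar = 0.8), 2e4))
  thin <- thick[seq(1, 2e4, by = 10)]
  expect_gt(effective_sample_size(matrix(thin)) / length(thin),
            effective_sample_size(matrix(thick)) / length(thick))
  expect_error(effective_sample_size(matrix(rep(1, 500))), "constant")
})

test_that("split halves partition the retained iterations", {
  x <- make_chains(list(matrix(as.numeric(1:4)), matrix(as.numeric(5:8))))
  h <- split_halves(x)
  expect_equal(as.vector(h$moment_half$draws[, 1, 1]), c(1, 2))
  expect_equal(as.vector(h$bridge_half$draws[, 1, 1]), c(3, 4))
  expect_equal(as.vector(h$bridge_half$draws[, 1, 2]), c(7, 8))
  # union of halves equals the original draws as multisets
  both <- c(as.matrix(h$moment_half), as.matrix(h$bridge_half))
  expect_equal(sort(both), sort(as.vector(x$draws)))
  # odd iteration count: first iteration dropped with a warning
  odd <- make_chains(list(matrix(as.numeric(1:5))))
  expect_warning(ho <- split_halves(odd), "odd")
  expect_equal(as.vector(ho$moment_half$draws[, 1, 1]), c(2, 3))
})

test_that("the sampler is reproducible under a seed", {
  fx <- pair_clustering_fixture()
  gen <- pc_dataset(I = 4)
  a <- sample_posterior(fx$model, gen$data, n_chains = 2, n_iter = 50,
                        burnin = 50, seed = 7)
  b <- sample_posterior(fx$model, gen$data, n_chains = 2, n_iter = 50,
                        burnin = 50, seed = 7)
  expect_identical(a$draws, b$draws)
  c_ <- sample_posterior(fx$model, gen$data, n_chains = 2, n_iter = 50,
                         burnin = 50, seed = 8)
  expect_false(identical(a$draws, c_$draws))
})

test_that("prior-only sampling recovers the standard normal mu prior", {
  # J = 0 data: the posterior is the prior; mu margins are N(0, 1)
  spec <- binomial_spec()
  m <- latent_trait_model(spec)
  data <- mpt_counts(matrix(0L, 2, 2), spec)
  ch <- sample_posterior(m, data, n_chains = 2, n_iter = 2000,
                         burnin = 1000, thin = 2, seed = 11)
  mu <- as.matrix(ch)[, "mu[p]"]
  ess <- effective_sample_size(ch)["mu[p]"]
  expect_lt(abs(mean(mu)), 3 / sqrt(ess))
  expect_equal(sd(mu), 1, tolerance = 0.1)
})

test_that("posterior moments match dense-grid quadrature on a small toy", {
  # P = 1, I = 2 binomial toy: compare sampler moments of mu with a
  # hand-written quadrature oracle over (mu, xi_trans, omega_1, omega_2)
  spec <- binomial_spec()
  m <- latent_trait_model(spec)
  counts_hit <- c(15L, 8L)
  data <- mpt_counts(cbind(counts_hit, 20L - counts_hit), spec)

  g <- seq(-5, 5, length.out = 41)
  grid <- as.matrix(expand.grid(g, g, g, g))
  w <- exp(toy_lp_by_hand(grid, counts_hit, 20))
  mu_mean <- sum(w * grid[, 1]) / sum(w)
  mu_sd <- sqrt(sum(w * (grid[, 1] - mu_mean)^2) / sum(w))

  ch <- sample_posterior(m, data, n_chains = 3, n_iter = 3000,
                         burnin = 1500, thin = 2, seed = 12)
  expect_lt(max(rhat(ch)), 1.05)
  mu <- as.matrix(ch)[, "mu[p]"]
  ess <- effective_sample_size(ch)["mu[p]"]
  expect_lt(abs(mean(mu) - mu_mean), 3 * mu_sd / sqrt(ess))
  expect_equal(sd(mu), mu_sd, tolerance = 0.1)
})

test_that("chains round-trip through the CSV archive", {
  fx <- pair_clustering_fixture()
  gen <- pc_dataset(I = 3)
  ch <- sample_posterior(fx$model, gen$data, n_chains = 2, n_iter = 40,
                         burnin = 40, seed = 3)
  f <- tempfile(fileext = ".csv")
  write_chains(ch, f)
  back <- read_chains(f)
  expect_equal(back$n_chains, 2)
  expect_equal(back$labels, ch$labels)
  expect_equal(as.matrix(back), as.matrix(ch), tolerance = 1e-12)
  expect_equal(back$seed, 3)
})
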