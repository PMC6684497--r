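test_that("xi transform: values, Jacobian, and round trip", {
  x <- xi_from_trans(c(0, 0), 10)
  expect_equal(x$xi, c(5, 5))
  expect_equal(x$log_jacobian, 2 * log(10 * dnorm(0)))
  expect_equal(log(10 * dnorm(0)), 1.3836, tolerance = 1e-4)
  xt <- c(-1.7, 0.2, 2.4)
  expect_equal(trans_from_xi(xi_from_trans(xt, 3)$xi, 3), xt,
               tolerance = 1e-12)
  expect_error(xi_from_trans(0, -1), "positive")
})

test_that("participant-level parameters follow the probit shift structure", {
  fx <- pair_clustering_fixture()
  m <- fx$model
  st <- list(mu = c(0, 0, 0), xi_trans = c(0, 0, 0), delta = c(1, 0, 0),
             omega = matrix(0, 2, 3))
  # mu = 0, omega = 0, delta_c = 1: condition means are +/- delta/2
  th1 <- theta_for_participant(st, m, 1, 1)
  th2 <- theta_for_participant(st, m, 1, 2)
  expect_equal(unname(th1["c"]), pnorm(-0.5))
  expect_equal(unname(th2["c"]), pnorm(0.5))
  expect_equal(unname(th1[c("r", "u")]), c(.5, .5))
  # zero scale: theta identical across participants despite omega
  st2 <- list(mu = c(.3, -.2, 0), xi_trans = c(-Inf, -Inf, -Inf),
              delta = c(0, 0, 0), omega = matrix(rnorm(6), 2, 3))
  st2$xi_trans <- rep(-8, 3)  # xi ~ 0 numerically
  expect_equal(theta_for_participant(st2, m, 1, 1),
               theta_for_participant(st2, m, 2, 1), tolerance = 1e-9)
  expect_error(theta_for_participant(st, m, 1, 3), "condition")
})

test_that("delta prior presets and design validation", {
  spec <- pc_spec()
  expect_equal(latent_trait_model(spec, 2, "c", "narrow")$sigma_delta, 0.52)
  expect_equal(latent_trait_model(spec, 2, "c", "medium")$sigma_delta, 0.84)
  expect_equal(latent_trait_model(spec, 2, "c", "wide")$sigma_delta, 1.28)
  expect_equal(latent_trait_model(spec, 2, "c", 0.3)$sigma_delta, 0.3)
  m <- latent_trait_model(spec)
  expect_equal(m$nu, 4)  # P + 1
  expect_error(latent_trait_model(spec, 1, "c"), "two-condition")
  expect_error(latent_trait_model(spec, 2, "zz"), "unknown parameters")
})

test_that("group-level factor matches the analytic P = 1 value", {
  expect_equal(log_group_level_factor(matrix(0, 1, 1), 2), log(0.5))
  # monotone decrease as the determinant grows
  v1 <- log_group_level_factor(matrix(0.5, 1, 1), 2)
  v2 <- log_group_level_factor(matrix(1.5, 1, 1), 2)
  expect_gt(v1, v2)
})

test_that("group-level factor equals the inverse-Wishart Monte Carlo integral", {
  # P = 2, I = 3: E_Q[prod_i N(omega_i; 0, Q)] under Q ~ IW(nu, I_2)
  set.seed(31)
  P <- 2; I <- 3; nu <- P + 1
  Omega <- matrix(rnorm(I * P, 0, 0.8), I, P)
  n_mc <- 2e5
  W <- rWishart(n_mc, nu, diag(P))  # Q = W^{-1} ~ IW(nu, I)
  vals <- vapply(seq_len(n_mc), function(s) {
    Wi <- W[, , s]  # = Q^{-1}
    dt <- Wi[1, 1] * Wi[2, 2] - Wi[1, 2]^2
    exp(-I * P / 2 * log(2 * pi) + I / 2 * log(dt) -
          0.5 * sum(diag(Wi %*% crossprod(Omega))))
  }, 0)
  mc <- mean(vals)
  se <- sd(vals) / sqrt(n_mc)
  expect_lt(abs(exp(log_group_level_factor(Omega, nu)) - mc), 3 * se)
})

test_that("posterior reduces to priors when there are no observations", {
  spec <- binomial_spec()
  m <- latent_trait_model(spec)
  # J = 0: a single empty multinomial carries no information
  data <- mpt_counts(matrix(0L, 1, 2), spec)
  st <- list(mu = 0.4, xi_trans = -0.3, delta = numeric(0),
             omega = matrix(0.7, 1, 1))
  got <- log_unnormalized_posterior(st, data, m)
  want <- log_group_level_factor(st$omega, m$nu) +
    dnorm(0.4, log = TRUE) + dnorm(-0.3, log = TRUE)
  expect_equal(got, want)
})

test_that("posterior is invariant to participant reordering", {
  fx <- pair_clustering_fixture()
  gen <- pc_dataset(I = 7)
  set.seed(5)
  st <- list(mu = rnorm(3, 0, .4), xi_trans = rnorm(3, 0, .4),
             delta = rnorm(3, 0, .3), omega = matrix(rnorm(21, 0, .5), 7, 3))
  v1 <- log_unnormalized_posterior(st, gen$data, fx$model)
  perm <- sample(7)
  st2 <- st
  st2$omega <- st$omega[perm, ]
  d2 <- gen$data
  d2$counts <- gen$data$counts[perm, , , drop = FALSE]
  expect_equal(log_unnormalized_posterior(st2, d2, fx$model), v1)
})

test_that("compiled evaluator agrees with the reference implementation", {
  fx <- pair_clustering_fixture()
  gen <- pc_dataset(I = 6)
  set.seed(8)
  for (rep in 1:10) {
    st <- list(mu = rnorm(3, 0, .6), xi_trans = rnorm(3, 0, .6),
               delta = rnorm(3, 0, .4),
               omega = matrix(rnorm(18, 0, .6), 6, 3))
    expect_equal(lt_log_posterior(pack_state(st), fx$model, gen$data),
                 log_unnormalized_posterior(st, gen$data, fx$model),
                 tolerance = 1e-9)
  }
  # impossible data: -Inf from both paths, never NaN
  st$mu <- c(40, 0, 0)  # theta_c = 1 numerically, some cells impossible
  v <- lt_log_posterior(pack_state(st), fx$model, gen$data)
  expect_identical(v, log_unnormalized_posterior(st, gen$data, fx$model))
})

test_that("marginalized posterior integrates to the non-marginalized value", {
  # P = 1, I = 1 binomial toy: integrate exp(log posterior) over
  # (mu, xi_trans, omega) by dense grid quadrature and compare with a
  # Monte Carlo average of the likelihood over the full prior chain
  # (mu, xi, omega | Q, Q) -- the unmarginalized marginal likelihood
  spec <- binomial_spec()
  m <- latent_trait_model(spec)
  data <- mpt_counts(matrix(c(13L, 7L), 1, 2), spec)

  g <- seq(-6, 6, length.out = 81)
  h <- g[2] - g[1]
  grid <- as.matrix(expand.grid(g, g, g))
  quad <- sum(exp(lt_log_posterior(grid, m, data))) * h^3

  set.seed(9)
  n_mc <- 4e5
  Qd <- 1 / rgamma(n_mc, shape = m$nu / 2, rate = 0.5)  # IW(nu, 1), P = 1
  mu <- rnorm(n_mc)
  xi <- runif(n_mc, 0, m$xi_max)
  om <- rnorm(n_mc, 0, sqrt(Qd))
  th <- pnorm(mu + xi * om)
  lik <- dbinom(13, 20, th)
  mc <- mean(lik)
  se <- sd(lik) / sqrt(n_mc)
  expect_lt(abs(quad - mc), 3 * se)
})
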