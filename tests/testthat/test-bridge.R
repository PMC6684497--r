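test_that("warp moments recover location and scale", {
  set.seed(41)
  x <- matrix(rnorm(3e5), ncol = 3)
  m <- estimate_moments(x)
  expect_lt(max(abs(m$v)), 0.05)
  expect_lt(max(abs(m$R - diag(3))), 0.05)
  # hand-computed four-point case
  pts <- rbind(c(0, 0), c(2, 0), c(0, 2), c(2, 2))
  m4 <- estimate_moments(pts)
  expect_equal(m4$v, c(1, 1))
  expect_equal(m4$R %*% t(m4$R), cov(pts), ignore_attr = TRUE)
  # rank deficiency: fewer draws than dimensions
  expect_error(estimate_moments(matrix(rnorm(6), 2, 3)), "more draws")
  expect_error(estimate_moments(cbind(rnorm(50), 1)), "rank deficient")
})

test_that("warp terms cancel exactly for a 1-D normal target", {
  # ptilde = c * N(m, s^2): l1 and l2 equal c for every draw
  logc <- 1.7
  m0 <- 2.3
  s0 <- 0.6
  lp <- function(x) logc + dnorm(x[, 1], m0, s0, log = TRUE)
  mom <- structure(list(v = m0, R = matrix(s0), log_det_R = log(s0), d = 1),
                   class = "warp_moments")
  set.seed(42)
  psi <- matrix(rnorm(200, m0, s0))
  eta <- matrix(rnorm(200))
  for (method in c("warp3", "warp2")) {
    l1 <- warped_log_density_terms(psi, mom, lp, method)
    l2 <- proposal_log_terms(eta, mom, lp, method)
    expect_equal(l1, rep(logc, 200), tolerance = 1e-10)
    expect_equal(l2, rep(logc, 200), tolerance = 1e-10)
  }
})

test_that("proposal terms: center point and mirror symmetry", {
  set.seed(43)
  lp <- function(x) -0.5 * rowSums((x - 1)^2) - rowSums(abs(x - 1)) / 3
  mom <- estimate_moments(matrix(rnorm(400, 1), ncol = 2))
  # eta = 0: value = log(|R| ptilde(v)) - log g(0)
  v0 <- proposal_log_terms(matrix(0, 1, 2), mom, lp, "warp3")
  want <- mom$log_det_R + lp(matrix(mom$v, 1)) + log(2 * pi)
  expect_equal(v0, want)
  # mixture symmetry: identical for eta and -eta
  e <- matrix(rnorm(20), 10, 2)
  expect_equal(proposal_log_terms(e, mom, lp, "warp3"),
               proposal_log_terms(-e, mom, lp, "warp3"))
})

test_that("symmetric posteriors collapse the mirror average", {
  # target symmetric about v: both mirror terms agree, so warp3 equals
  # warp2 pointwise on the posterior draws
  lp <- function(x) -0.25 * rowSums((x - 3)^2)
  mom <- structure(list(v = c(3, 3), R = diag(2), log_det_R = 0, d = 2),
                   class = "warp_moments")
  psi <- matrix(rnorm(40, 3), 20, 2)
  expect_equal(warped_log_density_terms(psi, mom, lp, "warp3"),
               warped_log_density_terms(psi, mom, lp, "warp2"))
})

test_that("iterative scheme: fixed points, worked example, equivariance", {
  # constant l values: estimate equals the constant after one iteration
  r <- iterative_bridge(rep(log(4), 5), rep(log(4), 7), 0.5, 0.5, init = 0)
  expect_equal(r$log_ml, log(4), tolerance = 1e-9)
  expect_true(r$converged)
  # hand-iterated worked example
  r2 <- iterative_bridge(log(c(1, 3)), log(c(2, 2)), 0.5, 0.5, init = 0)
  expect_equal(exp(r2$log_ml), 1.866198, tolerance = 1e-4)
  # scale equivariance: shifting all log l by a shifts the estimate by a
  a <- 3.7
  r3 <- iterative_bridge(log(c(1, 3)) + a, log(c(2, 2)) + a, 0.5, 0.5,
                         init = a)
  expect_equal(r3$log_ml, r2$log_ml + a, tolerance = 1e-8)
  # degenerate input
  expect_error(iterative_bridge(-Inf, -Inf, .5, .5), "overlap")
  # non-convergence is flagged, not raised
  r4 <- iterative_bridge(log(c(1, 3)), log(c(2, 2)), .5, .5, init = 0,
                         max_iter = 2, tol = 1e-14)
  expect_false(r4$converged)
})

test_that("warped draws have matched first three moments", {
  # the warp ladder: eta = sign * R^{-1}(psi - v) applied to the bridge
  # half, moments from the moment half, on a skewed target
  set.seed(44)
  n <- 4e4
  draws <- cbind(rgamma(n, 4, 2), rnorm(n, -1, 2) + 0.3 * rgamma(n, 2, 1))
  mom <- estimate_moments(draws[seq_len(n / 2), ])
  half <- draws[n / 2 + seq_len(n / 2), ]
  eta <- t(forwardsolve(mom$R, t(half) - mom$v))
  sgn <- sample(c(-1, 1), n / 2, replace = TRUE)
  eta <- eta * sgn
  expect_lt(max(abs(colMeans(eta))), 0.05)
  expect_lt(max(abs(cov(eta) - diag(2))), 0.05)
  third <- colMeans(sweep(eta, 2, colMeans(eta))^3)
  expect_lt(max(abs(third)), 0.1)
})

test_that("warping preserves the normalizing constant (1-D quadrature)", {
  # integrate the warped mixture density over eta and the unwarped
  # density over psi; both must equal the target's normalizing constant
  logc <- 0.9
  lp <- function(x) logc + dgamma(x[, 1], 3, 1.5, log = TRUE)
  set.seed(45)
  mom <- estimate_moments(matrix(rgamma(5000, 3, 1.5), ncol = 1))
  unwarped <- integrate(function(t) exp(lp(matrix(t))), 0, Inf)$value
  warped <- integrate(function(e) {
    vapply(e, function(ei) {
      ps <- mom$v + mom$R[1, 1] * c(-ei, ei)
      mom$R[1, 1] / 2 * sum(exp(lp(matrix(ps))))
    }, 0)
  }, -Inf, Inf)$value
  expect_equal(warped, unwarped, tolerance = 1e-6)
  expect_equal(unwarped, exp(logc), tolerance = 1e-6)
})

test_that("bridge sampler recovers a known 2-D normalizing constant", {
  logc <- log(7.3)
  lp <- function(x) {
    logc + dnorm(x[, 1], 1, sqrt(0.5), log = TRUE) +
      dnorm(x[, 2], 2, sqrt(2), log = TRUE)
  }
  set.seed(46)
  draws <- cbind(rnorm(8000, 1, sqrt(0.5)), rnorm(8000, 2, sqrt(2)))
  for (method in c("warp0", "warp2", "warp3")) {
    br <- bridge_sampler(draws, lp, method = method, n_repetitions = 3,
                         seed = 1)
    expect_equal(br$log_ml, logc, tolerance = 0.02)
    expect_true(br$all_converged)
  }
})

test_that("repetitions with identical seeds are identical", {
  lp <- function(x) dnorm(x[, 1], log = TRUE) + dnorm(x[, 2], log = TRUE)
  set.seed(47)
  draws <- matrix(rnorm(8000), ncol = 2)
  a <- bridge_sampler(draws, lp, n_repetitions = 2, seed = 9)
  b <- bridge_sampler(draws, lp, n_repetitions = 2, seed = 9)
  expect_identical(sapply(a$estimates, `[[`, "log_ml"),
                   sapply(b$estimates, `[[`, "log_ml"))
  c_ <- bridge_sampler(draws, lp, n_repetitions = 2, seed = 10)
  expect_false(identical(a$log_ml, c_$log_ml))
})

test_that("a model bridged under different seeds is self-consistent", {
  # BF(M, M) = 1 within repetition noise
  fx <- pair_clustering_fixture()
  gen <- pc_dataset(I = 5)
  ch <- sample_posterior(fx$model, gen$data, n_chains = 2, n_iter = 1200,
                         burnin = 1000, thin = 2, seed = 13)
  b1 <- estimate_log_ml(fx$model, gen$data, ch, n_repetitions = 5,
                        seed = 1)
  b2 <- estimate_log_ml(fx$model, gen$data, ch, n_repetitions = 5,
                        seed = 2)
  spread <- max(diff(b1$range), diff(b2$range))
  expect_lt(abs(bayes_factor(b1$log_ml, b2$log_ml)), 3 * spread)
})

test_that("bridge results serialize to JSON", {
  skip_if_not_installed("jsonlite")
  lp <- function(x) dnorm(x[, 1], log = TRUE) + dnorm(x[, 2], log = TRUE)
  set.seed(48)
  br <- bridge_sampler(matrix(rnorm(4000), ncol = 2), lp,
                       n_repetitions = 2, seed = 3)
  f <- tempfile(fileext = ".json")
  write_bridge_result(br, f)
  obj <- jsonlite::read_json(f)
  expect_equal(obj$summary$median_log_ml, br$log_ml, tolerance = 1e-12)
  expect_length(obj$repetitions, 2)
})
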