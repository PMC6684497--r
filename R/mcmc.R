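#' Posterior sampling for latent-trait MPT models
#'
#' Blocked adaptive random-walk Metropolis sampler targeting the
#' Q-marginalized posterior of the unbounded state
#' `psi = (mu, xi_trans, delta, omega_1, ..., omega_I)`. Each sweep
#' updates (a) the shared block `(mu, xi_trans, delta)` jointly, (b) all
#' per-participant random-effect blocks `omega_i` (their full
#' conditionals are mutually independent given the shared block and the
#' unscaled covariance `Q`), and (c) `Q` by a conjugate Gibbs draw from
#' `InvWishart(nu + I, Omega'Omega + I_P)`. `Q` is retained only to aid
#' mixing and is discarded before bridging: the retained `psi` margins
#' coincide with the Q-marginalized posterior that the bridge evaluates.
#'
#' Proposal scales adapt toward an acceptance rate of 0.23 during
#' burn-in and are frozen afterwards, so retained draws form a Markov
#' chain.
#'
#' @param model an `lt_model`.
#' @param data an `mpt_counts` object.
#' @param n_chains number of chains (>= 2 for diagnostics).
#' @param n_iter retained iterations per chain (after burn-in and
#'   thinning).
#' @param burnin discarded adaptation sweeps per chain.
#' @param thin keep every `thin`-th post-burn-in sweep.
#' @param seed integer; chains are seeded reproducibly from it.
#' @param init_sd spread of the overdispersed start values.
#' @return an object of class `mpt_chains`: `draws` is an
#'   `n_iter x d x n_chains` array with dimension labels, plus the
#'   settings, seed, and acceptance-rate summaries.
#' @export
sample_posterior <- function(model, data, n_chains = 3L, n_iter = 2000L,
                             burnin = 1000L, thin = 1L, seed = 1L,
                             init_sd = 1) {
  stopifnot(n_iter >= 1L, burnin >= 0L, thin >= 1L, n_chains >= 1L)
  I <- data$I
  P <- model$P
  F_ <- n_free_delta(model)
  d <- state_dim(model, I)
  labels <- state_labels(model, I)
  cst <- lt_constants(model, data)
  seeds <- derive_seeds(seed, n_chains)

  draws <- array(NA_real_, c(n_iter, d, n_chains),
                 dimnames = list(NULL, labels, paste0("chain", 1:n_chains)))
  acc <- matrix(NA_real_, n_chains, 2,
                dimnames = list(NULL, c("shared_block", "omega_blocks")))

  for (ch in seq_len(n_chains)) {
    set.seed(seeds[ch])
    res <- run_chain(model, data, cst, n_iter, burnin, thin, init_sd)
    draws[, , ch] <- res$draws
    acc[ch, ] <- res$acceptance
  }

  structure(list(draws = draws, labels = labels,
                 n_chains = n_chains, n_iter = n_iter,
                 settings = list(burnin = burnin, thin = thin,
                                 init_sd = init_sd),
                 seed = seed, chain_seeds = seeds, acceptance = acc,
                 model = model),
            class = "mpt_chains")
}

run_chain <- function(model, data, cst, n_iter, burnin, thin, init_sd) {
  I <- data$I
  P <- model$P
  F_ <- n_free_delta(model)
  d_shared <- 2L * P + F_

  # overdispersed start values for the identified parameters (mu,
  # delta); the random-effect scale starts moderate with small omega so
  # that heterogeneity grows likelihood-aligned instead of the chain
  # starting inside the xi ~ 0 funnel, where it can become metastable
  state <- list(mu = stats::rnorm(P, 0, init_sd),
                xi_trans = stats::rnorm(P, 0, 0.5),
                delta = stats::rnorm(F_, 0, model$sigma_delta),
                omega = matrix(stats::rnorm(I * P, 0, 0.1), I, P))
  psi <- pack_state(state)
  ll_pp <- lt_loglik_participants(psi, model, data, cst)[1, ]
  if (!all(is.finite(ll_pp))) {
    for (try in 1:50) {
      state$omega <- matrix(stats::rnorm(I * P, 0, 0.2), I, P)
      state$mu <- stats::rnorm(P, 0, 0.3)
      psi <- pack_state(state)
      ll_pp <- lt_loglik_participants(psi, model, data, cst)[1, ]
      if (all(is.finite(ll_pp))) break
    }
    if (!all(is.finite(ll_pp)))
      stop("could not find a starting state with finite log-posterior")
  }
  Q <- diag(P)

  ls_shared <- log(2.38 / sqrt(d_shared))
  ls_omega <- rep(log(2.38 / sqrt(P)), I)
  ls_scale <- log(0.3)
  n_sweeps <- burnin + n_iter * thin
  out <- matrix(NA_real_, n_iter, length(psi))
  acc_shared <- 0
  acc_omega <- 0
  n_kept_sweeps <- 0

  # covariance adaptation (shared block): empirical covariance of the
  # burn-in history shapes the proposal, refreshed periodically and
  # frozen with the scales when adaptation ends
  hist_shared <- matrix(NA_real_, burnin, d_shared)
  L_shared <- diag(d_shared)

  shared_logprior <- function(st) {
    -0.5 * sum(st$mu^2) - 0.5 * sum(st$xi_trans^2) -
      sum(st$delta^2) / (2 * model$sigma_delta^2)
  }
  lp_shared <- shared_logprior(state)

  for (t in seq_len(n_sweeps)) {
    adapting <- t <= burnin
    gamma <- if (adapting) min(0.5, 3 / sqrt(t)) else 0

    ## block A: shared (mu, xi_trans, delta); repeated within the sweep
    ## because this 2P+F-dimensional block limits mixing and one
    ## evaluation is cheap relative to the rest of the sweep
    for (rep_a in seq_len(4L)) {
      prop <- state
      step <- exp(ls_shared) *
        as.vector(L_shared %*% stats::rnorm(d_shared))
      prop$mu <- state$mu + step[seq_len(P)]
      prop$xi_trans <- state$xi_trans + step[P + seq_len(P)]
      if (F_) prop$delta <- state$delta + step[2 * P + seq_len(F_)]
      ll_prop <- lt_loglik_participants(pack_state(prop), model, data,
                                        cst)[1, ]
      lp_prop <- shared_logprior(prop)
      a <- sum(ll_prop) + lp_prop - sum(ll_pp) - lp_shared
      alpha <- min(1, exp(a))
      if (!is.finite(alpha)) alpha <- 0
      if (stats::runif(1) < alpha) {
        state <- prop
        ll_pp <- ll_prop
        lp_shared <- lp_prop
      }
      if (adapting) ls_shared <- ls_shared + gamma * (alpha - 0.23)
      if (!adapting) acc_shared <- acc_shared + alpha / 4
    }

    ## omega blocks: all participants proposed at once, accepted per block
    Qinv <- chol2inv(chol(Q))
    prop_omega <- state$omega +
      matrix(stats::rnorm(I * P), I, P) * exp(ls_omega)
    prop_state <- state
    prop_state$omega <- prop_omega
    ll_prop <- lt_loglik_participants(pack_state(prop_state), model,
                                      data, cst)[1, ]
    pri_cur <- -0.5 * rowSums((state$omega %*% Qinv) * state$omega)
    pri_prop <- -0.5 * rowSums((prop_omega %*% Qinv) * prop_omega)
    a_i <- ll_prop + pri_prop - ll_pp - pri_cur
    alpha_i <- pmin(1, exp(a_i))
    alpha_i[!is.finite(a_i)] <- 0
    take <- stats::runif(I) < alpha_i
    if (any(take)) {
      state$omega[take, ] <- prop_omega[take, , drop = FALSE]
      ll_pp[take] <- ll_prop[take]
    }
    if (adapting) ls_omega <- ls_omega + gamma * (alpha_i - 0.23)
    if (!adapting) acc_omega <- acc_omega + mean(alpha_i)

    ## conjugate Gibbs draw for the unscaled covariance Q
    Q <- update_Q(state$omega, model$nu)
    Qinv <- chol2inv(chol(Q))

    ## exact recentering of mu along the unidentified mu/omega ridge:
    ## conditional on zeta_i = mu + xi * omega_i (so every theta stays
    ## fixed and the likelihood drops out), mu is Gaussian with
    ## precision I_P + I * M, M = Diag(1/xi) Q^{-1} Diag(1/xi); the
    ## change of variables (mu, omega) -> (mu, zeta) has a mu-free
    ## Jacobian, so this is a plain Gibbs draw
    xi <- model$xi_max * stats::pnorm(state$xi_trans)
    M <- Qinv / outer(xi, xi)
    Lam <- diag(P) + I * M
    zeta_sum <- I * state$mu + colSums(state$omega) * xi
    ch_lam <- chol(Lam)
    mu_new <- as.vector(
      backsolve(ch_lam, backsolve(ch_lam, M %*% zeta_sum,
                                  transpose = TRUE)) +
        backsolve(ch_lam, stats::rnorm(P)))
    state$omega <- sweep(state$omega, 2, (state$mu - mu_new) / xi, "+")
    state$mu <- mu_new
    lp_shared <- shared_logprior(state)

    ## scale move on the second unidentified ridge: xi_p -> xi_p e^a,
    ## omega_.p -> omega_.p e^-a, Q -> D^-1 Q D^-1 (D = Diag(e^a))
    ## keeps theta and the omega density's quadratic form fixed; the
    ## omega normalizing constant cancels the omega Jacobian, so the
    ## acceptance ratio involves only the xi_trans prior (with its
    ## probit Jacobian) and the inverse-Wishart prior on Q -- it does
    ## not degrade with the number of participants
    a_s <- exp(ls_scale) * stats::rnorm(P)
    xi <- model$xi_max * stats::pnorm(state$xi_trans)
    xi_new <- xi * exp(a_s)
    if (all(xi_new < model$xi_max)) {
      xt_new <- stats::qnorm(xi_new / model$xi_max)
      a <- -0.5 * (sum(xt_new^2) - sum(state$xi_trans^2)) +
        sum(a_s + stats::dnorm(state$xi_trans, log = TRUE) -
              stats::dnorm(xt_new, log = TRUE)) +
        model$nu * sum(a_s) -
        0.5 * sum((exp(2 * a_s) - 1) * diag(Qinv))
      alpha_s <- min(1, exp(a))
      if (!is.finite(alpha_s)) alpha_s <- 0
      if (stats::runif(1) < alpha_s) {
        state$xi_trans <- xt_new
        state$omega <- sweep(state$omega, 2, exp(-a_s), "*")
        Q <- Q / outer(exp(a_s), exp(a_s))
        Qinv <- Qinv * outer(exp(a_s), exp(a_s))
        lp_shared <- shared_logprior(state)
      }
    } else alpha_s <- 0
    if (adapting) ls_scale <- ls_scale + gamma * (alpha_s - 0.3)

    if (adapting) {
      hist_shared[t, ] <- c(state$mu, state$xi_trans, state$delta)
      if (t >= 250L && t %% 100L == 0L) {
        cv <- stats::cov(hist_shared[max(1, t - 1000):t, , drop = FALSE])
        ch_ <- try(chol(cv + 1e-8 * diag(d_shared)), silent = TRUE)
        if (!inherits(ch_, "try-error")) L_shared <- t(ch_)
      }
    }

    if (!adapting) {
      n_kept_sweeps <- n_kept_sweeps + 1
      if (n_kept_sweeps %% thin == 0)
        out[n_kept_sweeps %/% thin, ] <- pack_state(state)
    }
  }

  list(draws = out,
       acceptance = c(acc_shared, acc_omega) / max(1, n_iter * thin))
}

#' Gibbs update of the unscaled group-level covariance
#'
#' Draws from the full conditional of `Q` given the random effects:
#' `InvWishart(nu + I, Omega'Omega + I_P)`.
#'
#' @param Omega I x P matrix of unscaled random effects.
#' @param nu prior degrees of freedom.
#' @return a P x P covariance draw.
#' @export
update_Q <- function(Omega, nu) {
  Omega <- as.matrix(Omega)
  stopifnot(all(is.finite(Omega)))
  P <- ncol(Omega)
  S <- crossprod(Omega) + diag(P)
  df <- nu + nrow(Omega)
  X <- stats::rWishart(1L, df, chol2inv(chol(S)))[, , 1]
  chol2inv(chol(X))
}

#' Potential scale reduction factor
#'
#' Classic Gelman--Rubin statistic per dimension, comparing
#' between-chain and within-chain variance. Values near 1 indicate
#' convergence; the conventional threshold is 1.05.
#'
#' @param chains an `mpt_chains` object (>= 2 chains).
#' @return named numeric vector of `R-hat` values, one per dimension.
#' @export
rhat <- function(chains) {
  stopifnot(inherits(chains, "mpt_chains"))
  if (chains$n_chains < 2L) stop("need at least 2 chains for R-hat")
  n <- chains$n_iter
  if (n < 4L) stop("need at least 4 iterations for R-hat")
  apply(chains$draws, 2, function(x) {
    # x: n x n_chains
    W <- mean(apply(x, 2, stats::var))
    B <- n * stats::var(colMeans(x))
    if (W <= 0) stop("zero within-chain variance in all chains")
    sqrt(((n - 1) / n * W + B / n) / W)
  })
}

#' @rdname rhat
#' @param threshold flag dimensions with `R-hat` at or above this value.
#' @return `rhat_flags` returns the labels of flagged dimensions
#'   (empty if all converged).
#' @export
rhat_flags <- function(chains, threshold = 1.05) {
  r <- rhat(chains)
  names(r)[r >= threshold]
}

# spectral density at frequency zero via AR model fitting (the classic
# time-series ESS estimator); x is one chain for one dimension
spec0_ar <- function(x) {
  v <- stats::var(x)
  if (v == 0) stop("constant chain")
  fit <- try(stats::ar(x, aic = TRUE,
                       order.max = min(100L, floor(length(x) / 4))),
             silent = TRUE)
  if (inherits(fit, "try-error") || !length(fit$ar)) return(v)
  fit$var.pred / (1 - sum(fit$ar))^2
}

#' Effective sample size
#'
#' Autocorrelation-adjusted number of independent draws per dimension,
#' estimated from the spectral density at frequency zero (AR-model
#' based), summed over chains.
#'
#' @param chains an `mpt_chains` object, or a numeric matrix
#'   (iterations x chains) for a single dimension.
#' @return per-dimension ESS (named vector), or a single number for a
#'   matrix input.
#' @export
effective_sample_size <- function(chains) {
  if (is.numeric(chains)) {
    x <- as.matrix(chains)
    return(sum(apply(x, 2, function(col)
      length(col) * stats::var(col) / spec0_ar(col))))
  }
  stopifnot(inherits(chains, "mpt_chains"))
  apply(chains$draws, 2, function(x) {
    sum(apply(as.matrix(x), 2, function(col)
      length(col) * stats::var(col) / spec0_ar(col)))
  })
}

#' Split retained draws into moment and bridge halves
#'
#' Per chain, the first half of the iterations forms the moment half
#' (used to estimate the warp location and scale) and the second half
#' forms the bridge half (used in the iterative scheme); the halves are
#' disjoint and jointly exhaustive. An odd iteration count drops the
#' first iteration with a warning.
#'
#' @param chains an `mpt_chains` object.
#' @return list with `moment_half` and `bridge_half`, both `mpt_chains`.
#' @export
split_halves <- function(chains) {
  stopifnot(inherits(chains, "mpt_chains"))
  n <- chains$n_iter
  if (n %% 2L == 1L) {
    warning("odd iteration count; dropping the first iteration")
    chains$draws <- chains$draws[-1L, , , drop = FALSE]
    n <- n - 1L
    chains$n_iter <- n
  }
  h <- n %/% 2L
  first <- chains
  first$draws <- chains$draws[seq_len(h), , , drop = FALSE]
  first$n_iter <- h
  second <- chains
  second$draws <- chains$draws[h + seq_len(h), , , drop = FALSE]
  second$n_iter <- h
  list(moment_half = first, bridge_half = second)
}

#' Flatten chains to a draw matrix
#'
#' @param x an `mpt_chains` object.
#' @param ... unused.
#' @return a (n_iter * n_chains) x d matrix, chains stacked.
#' @export
as.matrix.mpt_chains <- function(x, ...) {
  d <- dim(x$draws)
  out <- do.call(rbind, lapply(seq_len(d[3]), function(ch)
    matrix(x$draws[, , ch], nrow = d[1])))
  colnames(out) <- x$labels
  out
}

#' @export
print.mpt_chains <- function(x, ...) {
  cat("MPT posterior chains:", x$n_chains, "chains x", x$n_iter,
      "retained iterations,", length(x$labels), "dimensions\n")
  cat("  burn-in", x$settings$burnin, ", thin", x$settings$thin,
      ", seed", x$seed, "\n")
  cat("  mean acceptance: shared block",
      round(mean(x$acceptance[, 1]), 3), ", omega blocks",
      round(mean(x$acceptance[, 2]), 3), "\n")
  invisible(x)
}

#' Export / import chains as labeled CSV
#'
#' Column-labeled CSV with `chain` and `iteration` columns plus one
#' column per dimension; settings and seed are stored in `#`-comment
#' header lines so a bridging run can be reproduced from the file.
#'
#' @param chains an `mpt_chains` object.
#' @param file path.
#' @export
write_chains <- function(chains, file) {
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(c(
    paste0("# n_chains=", chains$n_chains, " n_iter=", chains$n_iter,
           " burnin=", chains$settings$burnin,
           " thin=", chains$settings$thin, " seed=", chains$seed)), con)
  df <- data.frame(
    chain = rep(seq_len(chains$n_chains), each = chains$n_iter),
    iteration = rep(seq_len(chains$n_iter), chains$n_chains))
  df <- cbind(df, as.data.frame(as.matrix(chains)))
  # dimension labels contain commas (e.g. omega[1,c]); keep them quoted
  utils::write.csv(df, con, row.names = FALSE)
  invisible(file)
}

#' @rdname write_chains
#' @export
read_chains <- function(file) {
  hdr <- readLines(file, n = 1L)
  meta <- as.list(stats::setNames(
    as.numeric(sub(".*=", "", strsplit(sub("^# *", "", hdr), " ")[[1]])),
    sub("=.*", "", strsplit(sub("^# *", "", hdr), " ")[[1]])))
  df <- utils::read.csv(file, comment.char = "#", check.names = FALSE)
  labels <- setdiff(names(df), c("chain", "iteration"))
  n_chains <- max(df$chain)
  n_iter <- max(df$iteration)
  draws <- array(NA_real_, c(n_iter, length(labels), n_chains),
                 dimnames = list(NULL, labels, paste0("chain", 1:n_chains)))
  for (ch in seq_len(n_chains))
    draws[, , ch] <- as.matrix(df[df$chain == ch, labels])
  structure(list(draws = draws, labels = labels, n_chains = n_chains,
                 n_iter = n_iter,
                 settings = list(burnin = meta$burnin, thin = meta$thin),
                 seed = meta$seed, acceptance = NULL, model = NULL),
            class = "mpt_chains")
}
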