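#' Define a hierarchical latent-trait MPT model
#'
#' The latent-trait approach places a multivariate normal group
#' distribution on the probit-transformed participant-level MPT
#' parameters. The covariance matrix is given a scaled inverse Wishart
#' prior: `Sigma = Diag(xi) Q Diag(xi)` with `Q ~ InvWishart(nu, I_P)`,
#' `nu = P + 1`, and independent `Uniform(0, xi_max)` priors on the
#' scaling parameters `xi`. Group means `mu` get independent standard
#' normal priors (uniform on the probability scale). With two conditions,
#' a condition-difference vector `delta` shifts the group mean by
#' `-delta/2` (condition 1) and `+delta/2` (condition 2) with one shared
#' random effect `omega_i` per participant; free components of `delta`
#' get zero-centered normal priors with standard deviation `sigma_delta`.
#'
#' The unbounded sampling space is
#' `psi = (mu, xi_trans, delta_free, omega_1, ..., omega_I)` where
#' `xi_trans = qnorm(xi / xi_max)`; its dimension is `P * (I + 2) + F`
#' with `F` the number of free difference parameters. The unscaled
#' covariance `Q` is integrated out of the posterior in closed form.
#'
#' @param spec an `mpt_model`.
#' @param n_cond number of conditions (1 or 2).
#' @param delta_free character vector naming the parameters whose
#'   between-condition difference is free (requires `n_cond = 2`), or NULL.
#' @param delta_prior `"narrow"`, `"medium"`, `"wide"` (probit-scale sds
#'   0.52, 0.84, 1.28, corresponding to small/medium/large effects on the
#'   probability scale around 0.5) or a positive number.
#' @param xi_max upper bound of the uniform prior on the scaling
#'   parameters (default 10).
#' @param nu Wishart degrees of freedom; defaults to `P + 1`, which makes
#'   the implied priors on the random-effect correlations uniform.
#' @return an object of class `lt_model`.
#' @export
latent_trait_model <- function(spec, n_cond = 1L, delta_free = NULL,
                               delta_prior = "medium", xi_max = 10,
                               nu = NULL) {
  stopifnot(inherits(spec, "mpt_model"))
  P <- length(spec$params)
  if (!n_cond %in% 1:2) stop("n_cond must be 1 or 2")
  if (xi_max <= 0) stop("xi_max must be positive")
  free <- rep(FALSE, P)
  if (!is.null(delta_free) && length(delta_free)) {
    if (n_cond == 1L)
      stop("difference parameters require a two-condition design")
    bad <- setdiff(delta_free, spec$params)
    if (length(bad)) stop("unknown parameters in delta_free: ",
                          paste(bad, collapse = ", "))
    free[match(delta_free, spec$params)] <- TRUE
  }
  sigma_delta <- delta_sd(delta_prior)
  structure(
    list(spec = spec, P = P, n_cond = as.integer(n_cond),
         delta_free = free, sigma_delta = sigma_delta,
         delta_prior = if (is.character(delta_prior)) delta_prior else "custom",
         xi_max = xi_max, nu = nu %||% (P + 1),
         cond_signs = if (n_cond == 2L) c(-0.5, 0.5) else 0),
    class = "lt_model")
}

delta_sd <- function(delta_prior) {
  if (is.numeric(delta_prior)) {
    if (delta_prior <= 0) stop("delta prior sd must be positive")
    return(delta_prior)
  }
  switch(match.arg(delta_prior, c("narrow", "medium", "wide")),
         narrow = 0.52, medium = 0.84, wide = 1.28)
}

#' @export
print.lt_model <- function(x, ...) {
  cat("Latent-trait MPT model on '", x$spec$name, "': P = ", x$P,
      ", ", x$n_cond, " condition(s)", sep = "")
  if (any(x$delta_free))
    cat(", free deltas: ",
        paste(x$spec$params[x$delta_free], collapse = ", "),
        " (sd ", x$sigma_delta, ")", sep = "")
  cat(", xi_max =", x$xi_max, ", nu =", x$nu, "\n")
  invisible(x)
}

n_free_delta <- function(model) sum(model$delta_free)

#' Dimension and labels of the unbounded parameter state
#'
#' @param model an `lt_model`.
#' @param I number of participants.
#' @return `state_dim` the total dimension `P*(I+2) + F`; `state_labels`
#'   a character vector naming each coordinate.
#' @export
state_dim <- function(model, I) {
  model$P * (I + 2L) + n_free_delta(model)
}

#' @rdname state_dim
#' @export
state_labels <- function(model, I) {
  p <- model$spec$params
  c(paste0("mu[", p, "]"), paste0("xi_trans[", p, "]"),
    if (any(model$delta_free)) paste0("delta[", p[model$delta_free], "]"),
    as.vector(t(outer(seq_len(I), p,
                      function(i, q) paste0("omega[", i, ",", q, "]")))))
}

#' Pack / unpack a parameter state
#'
#' A `ParameterState` is a list with components `mu` (length P),
#' `xi_trans` (length P), `delta` (length F, free differences only), and
#' `omega` (I x P matrix of unscaled random effects). `pack_state` lays it
#' out as a single numeric vector (participant-major for `omega`),
#' `unpack_state` inverts the layout.
#'
#' @param state a parameter-state list.
#' @export
pack_state <- function(state) {
  c(state$mu, state$xi_trans, state$delta, as.vector(t(state$omega)))
}

#' @rdname pack_state
#' @param psi numeric vector of length `state_dim(model, I)`.
#' @param model an `lt_model`.
#' @param I number of participants.
#' @export
unpack_state <- function(psi, model, I) {
  P <- model$P
  F_ <- n_free_delta(model)
  if (length(psi) != state_dim(model, I))
    stop("state vector has wrong length")
  list(mu = psi[seq_len(P)],
       xi_trans = psi[P + seq_len(P)],
       delta = if (F_) psi[2 * P + seq_len(F_)] else numeric(0),
       omega = matrix(psi[-seq_len(2 * P + F_)], I, P, byrow = TRUE))
}

#' Scaling parameters from their unbounded transform
#'
#' The bounded scaling parameters `xi in (0, xi_max)` enter the sampling
#' space as `xi_trans = qnorm(xi / xi_max)`. This returns
#' `xi = xi_max * pnorm(xi_trans)` together with the log-Jacobian of the
#' inverse map, `sum(log(xi_max) + dnorm(xi_trans, log = TRUE))`.
#'
#' @param xi_trans numeric vector.
#' @param xi_max positive scalar.
#' @return list with `xi` and `log_jacobian`.
#' @export
xi_from_trans <- function(xi_trans, xi_max) {
  if (!is.numeric(xi_max) || xi_max <= 0) stop("xi_max must be positive")
  list(xi = xi_max * stats::pnorm(xi_trans),
       log_jacobian = sum(log(xi_max) +
                            stats::dnorm(xi_trans, log = TRUE)))
}

#' @rdname xi_from_trans
#' @param xi vector in `(0, xi_max)`.
#' @export
trans_from_xi <- function(xi, xi_max) {
  if (any(xi <= 0 | xi >= xi_max)) stop("xi must lie in (0, xi_max)")
  stats::qnorm(xi / xi_max)
}

# difference vector embedded at the free positions, zeros elsewhere
embed_delta <- function(model, delta) {
  d <- numeric(model$P)
  d[model$delta_free] <- delta
  d
}

#' Participant-level MPT parameters implied by a state
#'
#' Returns `theta_i = pnorm(mu + sign_c * delta + xi * omega_i)`
#' componentwise, where `sign_c` is -1/2 for condition 1 and +1/2 for
#' condition 2 (0 in a one-condition design) and `delta` is embedded with
#' zeros at non-free parameters.
#'
#' @param state a parameter-state list (see [pack_state()]).
#' @param model an `lt_model`.
#' @param i participant index.
#' @param condition condition index.
#' @return probability vector of length P, entries in (0, 1).
#' @export
theta_for_participant <- function(state, model, i, condition = 1L) {
  if (condition < 1L || condition > model$n_cond)
    stop("condition index out of design")
  if (i < 1L || i > nrow(state$omega)) stop("participant index out of range")
  xi <- xi_from_trans(state$xi_trans, model$xi_max)$xi
  d <- embed_delta(model, state$delta)
  tp <- state$mu + model$cond_signs[condition] * d + xi * state$omega[i, ]
  stats::setNames(stats::pnorm(tp), model$spec$params)
}

#' Log of the Q-marginalized group-level factor
#'
#' Integrating the unscaled covariance matrix `Q` (inverse Wishart prior,
#' identity scale) out of the product of the random-effect densities
#' yields, in closed form,
#' \deqn{\frac{\Gamma_P((\nu+I)/2)}{\Gamma_P(\nu/2)} \,
#'   \pi^{-IP/2} \, |\Omega^\top\Omega + I_P|^{-(\nu+I)/2},}
#' where `Omega` stacks the participant random effects row-wise.
#'
#' @param Omega I x P matrix of unscaled random effects.
#' @param nu Wishart degrees of freedom.
#' @return the log of the marginalized factor.
#' @export
log_group_level_factor <- function(Omega, nu) {
  Omega <- as.matrix(Omega)
  if (!all(is.finite(Omega))) stop("Omega must be finite")
  P <- ncol(Omega)
  I <- nrow(Omega)
  M <- crossprod(Omega) + diag(P)
  ld <- determinant(M, logarithm = TRUE)
  if (ld$sign <= 0 || !is.finite(ld$modulus)) stop("non-finite determinant")
  lmvgamma((nu + I) / 2, P) - lmvgamma(nu / 2, P) -
    I * P / 2 * log(pi) - (nu + I) / 2 * as.numeric(ld$modulus)
}

#' Log unnormalized posterior density of the latent-trait model
#'
#' Evaluates, on the unbounded state `psi`, the sum of (a) all
#' participants' per-condition product-multinomial log-likelihoods, (b)
#' the Q-marginalized group-level factor, (c) the standard normal log
#' prior on `mu`, (d) the standard normal log density of `xi_trans` (the
#' uniform prior on `xi` times the Jacobian of the probit rescaling), and
#' (e) the zero-centered normal log priors on the free difference
#' parameters. The value is `-Inf` (never `NaN`) when a zero-probability
#' category has a positive count.
#'
#' This is the reference R implementation; the vectorized evaluator used
#' by the sampler and the bridge is [lt_log_posterior()].
#'
#' @param state a parameter-state list.
#' @param data an `mpt_counts` object.
#' @param model an `lt_model`.
#' @return the log unnormalized posterior density (a single number).
#' @export
log_unnormalized_posterior <- function(state, data, model) {
  I <- data$I
  if (nrow(state$omega) != I || ncol(state$omega) != model$P)
    stop("state dimensions do not match model/data")
  if (length(state$delta) != n_free_delta(model))
    stop("state has wrong number of free delta components")
  ll <- 0
  for (i in seq_len(I)) {
    for (cc in seq_len(data$n_cond)) {
      th <- theta_for_participant(state, model, i, cc)
      ll <- ll + log_likelihood(model$spec, data$counts[i, , cc], th)
      if (!is.finite(ll)) break
    }
    if (!is.finite(ll)) break
  }
  lp <- log_group_level_factor(state$omega, model$nu) +
    sum(stats::dnorm(state$mu, log = TRUE)) +
    sum(stats::dnorm(state$xi_trans, log = TRUE))
  if (length(state$delta))
    lp <- lp + sum(stats::dnorm(state$delta, 0, model$sigma_delta,
                                log = TRUE))
  ll + lp
}

#' Vectorized log unnormalized posterior
#'
#' Evaluates the same density as [log_unnormalized_posterior()] for every
#' row of a draw matrix at once (compiled implementation). This is the
#' callback the bridge sampler uses.
#'
#' @param psi numeric matrix, one state per row (layout of
#'   [pack_state()]).
#' @param model an `lt_model`.
#' @param data an `mpt_counts` object.
#' @return numeric vector of log densities, one per row.
#' @export
lt_log_posterior <- function(psi, model, data) {
  if (is.null(dim(psi))) psi <- matrix(psi, nrow = 1L)
  cst <- lt_constants(model, data)
  as.vector(cpp_lt_logpost(
    psi, cst$counts_flat, model$spec$V * 1.0, model$spec$W * 1.0,
    model$spec$branch_cat - 1L, model$P, data$I, data$n_cond,
    cst$cond_signs, cst$delta_map, model$xi_max, model$sigma_delta,
    cst$const_terms, cst$gf_coef, FALSE))
}

# per-participant log-likelihood matrix (no priors, no multinomial
# coefficients); used inside the MCMC sweeps where constants cancel
lt_loglik_participants <- function(psi, model, data, cst = NULL) {
  if (is.null(dim(psi))) psi <- matrix(psi, nrow = 1L)
  cst <- cst %||% lt_constants(model, data)
  cpp_lt_logpost(
    psi, cst$counts_flat, model$spec$V * 1.0, model$spec$W * 1.0,
    model$spec$branch_cat - 1L, model$P, data$I, data$n_cond,
    cst$cond_signs, cst$delta_map, model$xi_max, model$sigma_delta,
    cst$const_terms, cst$gf_coef, TRUE)
}

# precomputed constants shared by all density evaluations
lt_constants <- function(model, data) {
  P <- model$P
  I <- data$I
  nu <- model$nu
  ncat <- length(model$spec$cat_labels)
  counts_flat <- matrix(0, I, ncat * data$n_cond)
  for (cc in seq_len(data$n_cond))
    counts_flat[, (cc - 1) * ncat + seq_len(ncat)] <- data$counts[, , cc]
  # multinomial coefficients (data constant)
  mult <- 0
  for (cc in seq_len(data$n_cond)) for (k in seq_along(data$J)) {
    idx <- which(model$spec$cat_tree == k)
    n <- data$counts[, idx, cc, drop = FALSE]
    mult <- mult + data$I * lgamma(data$J[k] + 1) - sum(lgamma(n + 1))
  }
  const_terms <- mult +
    lmvgamma((nu + I) / 2, P) - lmvgamma(nu / 2, P) -
    I * P / 2 * log(pi) -
    P / 2 * log(2 * pi) - P / 2 * log(2 * pi) -
    n_free_delta(model) * (0.5 * log(2 * pi) + log(model$sigma_delta))
  dm <- rep(-1L, P)
  dm[model$delta_free] <- seq_len(n_free_delta(model)) - 1L
  list(counts_flat = counts_flat,
       cond_signs = as.numeric(model$cond_signs),
       delta_map = dm, const_terms = const_terms,
       gf_coef = (nu + I) / 2)
}
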