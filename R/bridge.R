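#' Warp moments from posterior draws
#'
#' Estimates the location vector `v` and the lower-triangular Cholesky
#' factor `R` (with `S = R R'` the sample covariance) that define the
#' warp transformation `eta = b * R^{-1} (psi - v)`.
#'
#' @param samples numeric matrix of draws, one per row; needs more rows
#'   than columns and a positive-definite sample covariance.
#' @return an object of class `warp_moments`: `v`, `R` (lower
#'   triangular, positive diagonal), `log_det_R`.
#' @export
estimate_moments <- function(samples) {
  samples <- as.matrix(samples)
  d <- ncol(samples)
  if (nrow(samples) <= d)
    stop("need more draws than dimensions to estimate the covariance")
  v <- colMeans(samples)
  S <- stats::cov(samples)
  Ru <- try(chol(S), silent = TRUE)
  if (inherits(Ru, "try-error"))
    stop("sample covariance is rank deficient (constant dimension?)")
  R <- t(Ru)
  structure(list(v = v, R = R, log_det_R = sum(log(diag(R))), d = d),
            class = "warp_moments")
}

# log density of the d-dimensional standard normal at each row of eta
log_g <- function(eta) {
  -ncol(eta) / 2 * log(2 * pi) - 0.5 * rowSums(eta^2)
}

#' Warped log density terms for posterior draws (l1)
#'
#' For each posterior draw `psi`, computes
#' `log l1 = log{ (|R|/2) [ptilde(2v - psi) + ptilde(psi)] } -
#'  log g(R^{-1}(psi - v))`,
#' the mixture form induced by the random sign of the warp; the two
#' mirror terms are combined by log-sum-exp. With `method = "warp2"` the
#' mirror term is omitted (plain moment-matched normal proposal); with
#' `"warp0"` no warping is applied (`v = 0`, `R = I`).
#'
#' @param psi matrix of posterior draws (one per row).
#' @param moments a `warp_moments` object.
#' @param log_post vectorized callback returning the log unnormalized
#'   posterior for each row of its matrix argument.
#' @param method `"warp3"`, `"warp2"`, or `"warp0"`.
#' @return numeric vector of `log l1` values (`-Inf` where both mirror
#'   terms vanish).
#' @export
warped_log_density_terms <- function(psi, moments, log_post,
                                     method = "warp3") {
  method <- match.arg(method, c("warp3", "warp2", "warp0"))
  psi <- as.matrix(psi)
  if (method == "warp0") return(log_post(psi) - log_g(psi))
  eta <- t(forwardsolve(moments$R, t(psi) - moments$v))
  lg <- log_g(eta)
  q1 <- log_post(psi)
  if (method == "warp2") return(moments$log_det_R + q1 - lg)
  mirror <- sweep(-psi, 2, 2 * moments$v, "+")   # 2v - psi
  q2 <- log_post(mirror)
  log(0.5) + moments$log_det_R + logsumexp2(q1, q2) - lg
}

#' Proposal log density terms (l2)
#'
#' For each standard-normal proposal draw `eta`, computes
#' `log l2 = log{ (|R|/2) [ptilde(v - R eta) + ptilde(v + R eta)] } -
#'  log g(eta)` (mirror term dropped for `"warp2"`; identity warp for
#' `"warp0"`).
#'
#' @param eta matrix of proposal draws (one per row).
#' @inheritParams warped_log_density_terms
#' @return numeric vector of `log l2` values.
#' @export
proposal_log_terms <- function(eta, moments, log_post, method = "warp3") {
  method <- match.arg(method, c("warp3", "warp2", "warp0"))
  eta <- as.matrix(eta)
  if (method == "warp0") return(log_post(eta) - log_g(eta))
  lg <- log_g(eta)
  shift <- eta %*% t(moments$R)                  # rows: (R eta)'
  plus <- sweep(shift, 2, moments$v, "+")
  qp <- log_post(plus)
  if (method == "warp2") return(moments$log_det_R + qp - lg)
  minus <- sweep(-shift, 2, moments$v, "+")
  qm <- log_post(minus)
  log(0.5) + moments$log_det_R + logsumexp2(qm, qp) - lg
}

#' Iterative bridge updating scheme
#'
#' Fixed-point iteration for the optimal-bridge estimate of a
#' normalizing constant, executed entirely in log space:
#' \deqn{\hat{Z}^{(t+1)} =
#'   \frac{D_2^{-1} \sum_r l_{2,r} / (s_1 l_{2,r} + s_2 \hat{Z}^{(t)})}
#'        {D_1^{-1} \sum_j 1 / (s_1 l_{1,j} + s_2 \hat{Z}^{(t)})}.}
#' Iteration stops when the absolute change of the log estimate falls
#' below `tol` or after `max_iter` iterations (flagged, not an error).
#'
#' @param log_l1 log of the `l1` values (length D1).
#' @param log_l2 log of the `l2` values (length D2).
#' @param s1,s2 positive weights summing to 1.
#' @param init initial guess for the log estimate; defaults to
#'   `median(log_l2)`.
#' @param tol convergence tolerance on the log estimate.
#' @param max_iter iteration cap.
#' @return list with `log_ml`, `iterations`, `converged`, `tol`.
#' @export
iterative_bridge <- function(log_l1, log_l2, s1 = 0.5, s2 = 0.5,
                             init = NULL, tol = 1e-10, max_iter = 1000L) {
  stopifnot(length(log_l1) >= 1L, length(log_l2) >= 1L,
            s1 > 0, s2 > 0, abs(s1 + s2 - 1) < 1e-12)
  if (all(!is.finite(log_l1)) || all(!is.finite(log_l2)))
    stop("all bridge terms are -Inf; the posterior and proposal do not overlap")
  D1 <- length(log_l1)
  D2 <- length(log_l2)
  ls1 <- log(s1)
  ls2 <- log(s2)
  logz <- init %||% stats::median(log_l2[is.finite(log_l2)])
  converged <- FALSE
  iter <- 0L
  for (iter in seq_len(max_iter)) {
    den2 <- logsumexp2(ls1 + log_l2, ls2 + logz)
    num <- logsumexp(log_l2 - den2) - log(D2)
    den1 <- logsumexp2(ls1 + log_l1, ls2 + logz)
    den <- logsumexp(-den1) - log(D1)
    new <- num - den
    if (is.finite(new) && abs(new - logz) < tol) {
      logz <- new
      converged <- TRUE
      break
    }
    logz <- new
  }
  list(log_ml = logz, iterations = iter, converged = converged, tol = tol)
}

# shared core: moment half -> warp moments, bridge half -> l1 terms,
# fresh proposal draws per repetition -> l2 terms, iterate
bridge_core <- function(moment_half, bridge_half, log_post,
                        method = "warp3", n_repetitions = 1L, seed = 1L,
                        ess = NULL, D2 = NULL, tol = 1e-10,
                        max_iter = 1000L, resplit = FALSE) {
  method <- match.arg(method, c("warp3", "warp2", "warp0"))
  d <- ncol(bridge_half)
  D1 <- nrow(bridge_half)
  D2 <- as.integer(D2 %||% D1)
  ess_used <- ess %||% D1
  s1 <- ess_used / (ess_used + D2)
  s2 <- 1 - s1
  seeds <- derive_seeds(seed, n_repetitions)

  moments <- estimate_moments(moment_half)
  log_l1 <- warped_log_density_terms(bridge_half, moments, log_post,
                                     method)
  all_draws <- if (resplit) rbind(moment_half, bridge_half) else NULL

  reps <- vector("list", n_repetitions)
  for (r in seq_len(n_repetitions)) {
    set.seed(seeds[r])
    if (resplit) {
      idx <- sample.int(nrow(all_draws), D1)
      moments <- estimate_moments(all_draws[-idx, , drop = FALSE])
      log_l1 <- warped_log_density_terms(all_draws[idx, , drop = FALSE],
                                         moments, log_post, method)
    }
    eta <- matrix(stats::rnorm(D2 * d), D2, d)
    log_l2 <- proposal_log_terms(eta, moments, log_post, method)
    it <- iterative_bridge(log_l1, log_l2, s1, s2, tol = tol,
                           max_iter = max_iter)
    reps[[r]] <- structure(
      list(log_ml = it$log_ml, iterations = it$iterations,
           converged = it$converged, tol = tol, D1 = D1, D2 = D2,
           ess_used = ess_used, method = method, repetition = r,
           seed = seeds[r]),
      class = "bridge_estimate")
  }
  lm <- vapply(reps, `[[`, 0, "log_ml")
  structure(list(estimates = reps, log_ml = stats::median(lm),
                 range = range(lm), method = method, D1 = D1, D2 = D2,
                 ess_used = ess_used, seed = seed,
                 all_converged = all(vapply(reps, `[[`, TRUE, "converged"))),
            class = "bridge_result")
}

#' Generic bridge sampler for an unnormalized density
#'
#' Estimates the log normalizing constant of `exp(log_post)` from draws
#' of the normalized density. The draw matrix is split in half: the
#' first half estimates the warp moments, the second half enters the
#' iterative scheme (`D1` draws); `D2 = D1` fresh standard-normal
#' proposal draws are generated per repetition from the recorded seed.
#'
#' @param samples matrix of draws from the (normalized) target, one per
#'   row; an odd row count drops the first row with a warning.
#' @param log_post vectorized log unnormalized density callback.
#' @param method `"warp3"` (moment + skew matched), `"warp2"` (moment
#'   matched), or `"warp0"` (no warping).
#' @param n_repetitions number of independent proposal-draw repetitions.
#' @param seed master seed.
#' @param ess optional effective sample size replacing `D1` in the
#'   optimal-bridge weights (for autocorrelated draws).
#' @param tol,max_iter passed to [iterative_bridge()].
#' @param resplit re-randomize the moment/bridge split per repetition
#'   (default: fixed first/second-half split; repetitions then differ in
#'   proposal draws only).
#' @return a `bridge_result`: per-repetition `bridge_estimate`s, the
#'   median `log_ml`, and the min--max range.
#' @export
bridge_sampler <- function(samples, log_post, method = "warp3",
                           n_repetitions = 1L, seed = 1L, ess = NULL,
                           tol = 1e-10, max_iter = 1000L,
                           resplit = FALSE) {
  samples <- as.matrix(samples)
  n <- nrow(samples)
  if (n %% 2L == 1L) {
    warning("odd draw count; dropping the first draw")
    samples <- samples[-1L, , drop = FALSE]
    n <- n - 1L
  }
  h <- n %/% 2L
  bridge_core(samples[seq_len(h), , drop = FALSE],
              samples[h + seq_len(h), , drop = FALSE],
              log_post, method, n_repetitions, seed, ess,
              tol = tol, max_iter = max_iter, resplit = resplit)
}

#' Log marginal likelihood of a latent-trait MPT model
#'
#' Warp-III (or Warp-0/II) bridge sampling estimate of the log marginal
#' likelihood from posterior chains. Per chain, the first half of the
#' iterations estimates the warp moments and the second half enters the
#' iterative scheme; the optimal-bridge weight `s1` replaces `D1` by the
#' median effective sample size of the bridge-half draws.
#'
#' @param model an `lt_model`.
#' @param data an `mpt_counts` object.
#' @param chains an `mpt_chains` object from [sample_posterior()]
#'   (convergence should be checked by the caller, e.g. via [rhat()]).
#' @inheritParams bridge_sampler
#' @return a `bridge_result`.
#' @export
estimate_log_ml <- function(model, data, chains, method = "warp3",
                            n_repetitions = 1L, seed = 1L, tol = 1e-10,
                            max_iter = 1000L, resplit = FALSE) {
  halves <- split_halves(chains)
  ess <- stats::median(effective_sample_size(halves$bridge_half))
  log_post <- function(psi) lt_log_posterior(psi, model, data)
  bridge_core(as.matrix(halves$moment_half),
              as.matrix(halves$bridge_half),
              log_post, method, n_repetitions, seed, ess,
              tol = tol, max_iter = max_iter, resplit = resplit)
}

#' @export
print.bridge_result <- function(x, ...) {
  cat("Bridge sampling estimate (", x$method, "): log ML = ",
      format(x$log_ml, digits = 6), "\n", sep = "")
  cat("  ", length(x$estimates), " repetition(s), range [",
      format(x$range[1], digits = 6), ", ",
      format(x$range[2], digits = 6), "]\n", sep = "")
  cat("  D1 =", x$D1, ", D2 =", x$D2, ", ESS used =",
      round(x$ess_used, 1),
      if (!x$all_converged) ", WARNING: not all repetitions converged",
      "\n")
  invisible(x)
}

#' Serialize a bridge result to JSON
#'
#' Per-repetition log marginal likelihoods, method, sizes, convergence
#' flags and seeds, plus a summary block with the median and min--max
#' range.
#'
#' @param x a `bridge_result`.
#' @param file path to write to.
#' @export
write_bridge_result <- function(x, file) {
  if (!requireNamespace("jsonlite", quietly = TRUE))
    stop("jsonlite is required to write JSON results")
  obj <- list(
    method = x$method, D1 = x$D1, D2 = x$D2, ess_used = x$ess_used,
    seed = x$seed,
    repetitions = lapply(x$estimates, function(e)
      list(log_ml = e$log_ml, iterations = e$iterations,
           converged = e$converged, seed = e$seed)),
    summary = list(median_log_ml = x$log_ml, min = x$range[1],
                   max = x$range[2]))
  jsonlite::write_json(obj, file, auto_unbox = TRUE, digits = NA)
  invisible(file)
}
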