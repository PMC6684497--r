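#' Enumerate the nested family of condition-difference models
#'
#' One model per subset of candidate difference parameters: each subset
#' frees those deltas and fixes the rest at zero, so `q` candidates give
#' `2^q` models. Labels join the freed parameter names with `-` (the
#' all-fixed model is labeled `"none"`). Prior model probabilities are
#' uniform by default.
#'
#' @param base an `lt_model` with a two-condition design.
#' @param candidate_deltas character vector of parameter names whose
#'   between-condition difference is under test.
#' @param prior_probs optional prior model probabilities (must be
#'   non-negative and sum to 1).
#' @return an object of class `mpt_model_set`: `models` (list of
#'   `lt_model`s), `labels`, `prior_probs`, and `membership`, a logical
#'   matrix (parameter x model) marking the models in which each
#'   candidate's delta is free.
#' @export
enumerate_nested_models <- function(base, candidate_deltas,
                                    prior_probs = NULL) {
  stopifnot(inherits(base, "lt_model"))
  if (!length(candidate_deltas)) stop("candidate set must be non-empty")
  if (anyDuplicated(candidate_deltas))
    stop("duplicate parameter names in candidate set")
  bad <- setdiff(candidate_deltas, base$spec$params)
  if (length(bad)) stop("unknown parameters: ", paste(bad, collapse = ", "))
  q <- length(candidate_deltas)
  subsets <- expand.grid(rep(list(c(TRUE, FALSE)), q))
  names(subsets) <- candidate_deltas
  M <- nrow(subsets)
  models <- vector("list", M)
  labels <- character(M)
  membership <- matrix(FALSE, q, M,
                       dimnames = list(candidate_deltas, NULL))
  for (m in seq_len(M)) {
    free <- candidate_deltas[unlist(subsets[m, ])]
    models[[m]] <- latent_trait_model(
      base$spec, n_cond = 2L,
      delta_free = if (length(free)) free else NULL,
      delta_prior = if (base$delta_prior == "custom") base$sigma_delta
                    else base$delta_prior,
      xi_max = base$xi_max, nu = base$nu)
    labels[m] <- if (length(free)) paste(free, collapse = "-") else "none"
    membership[free, m] <- TRUE
  }
  pp <- prior_probs %||% rep(1 / M, M)
  if (any(pp < 0) || abs(sum(pp) - 1) > 1e-12)
    stop("prior probabilities must be non-negative and sum to 1")
  structure(list(models = models, labels = labels, prior_probs = pp,
                 membership = membership),
            class = "mpt_model_set")
}

#' @export
print.mpt_model_set <- function(x, ...) {
  cat("Nested model set:", length(x$models), "models:",
      paste(x$labels, collapse = ", "), "\n")
  invisible(x)
}

#' Posterior model probabilities
#'
#' Bayes' rule over a fixed candidate set: the posterior probability of
#' each model is proportional to its marginal likelihood times its prior
#' probability. Computed stably as a max-shifted softmax of
#' `log_ml + log(prior)`; shifting all log marginal likelihoods by a
#' constant leaves the result unchanged.
#'
#' @param log_mls numeric vector of log marginal likelihoods.
#' @param priors prior model probabilities (default uniform).
#' @return probability vector summing to 1.
#' @export
posterior_model_probabilities <- function(log_mls,
                                          priors = rep(1 / length(log_mls),
                                                       length(log_mls))) {
  if (length(log_mls) != length(priors)) stop("length mismatch")
  if (any(priors < 0) || abs(sum(priors) - 1) > 1e-12)
    stop("priors must be non-negative and sum to 1")
  lp <- log_mls + log(priors)
  if (all(!is.finite(lp))) stop("all log marginal likelihoods are -Inf")
  m <- max(lp[is.finite(lp)])
  w <- exp(lp - m)
  w[!is.finite(lp)] <- 0
  out <- w / sum(w)
  names(out) <- names(log_mls)
  out
}

#' Log Bayes factor between two models
#'
#' `log BF_12 = log_ml_1 - log_ml_2`; antisymmetric in its arguments.
#' Helpers convert to the log10 scale or format the raw ratio
#' overflow-safely.
#'
#' @param log_ml_1,log_ml_2 log marginal likelihoods.
#' @return the log Bayes factor.
#' @export
bayes_factor <- function(log_ml_1, log_ml_2) {
  if (!is.finite(log_ml_1) || !is.finite(log_ml_2))
    stop("log marginal likelihoods must be finite")
  log_ml_1 - log_ml_2
}

#' @rdname bayes_factor
#' @param log_bf a log (natural) Bayes factor.
#' @export
format_bayes_factor <- function(log_bf) {
  l10 <- log_bf / log(10)
  if (abs(l10) < 6) return(format(exp(log_bf), digits = 4))
  e <- floor(l10)
  sprintf("%.1fe%+d", 10^(l10 - e), e)
}

#' Model-averaged inclusion probability
#'
#' Sum of the (posterior or prior) model probabilities of the models in
#' which a parameter's difference is free. Comparing posterior to prior
#' inclusion quantifies model-averaged evidence for a change in that
#' parameter.
#'
#' @param model_probs probability vector over models.
#' @param member_mask logical vector marking member models.
#' @return the inclusion probability.
#' @export
inclusion_probability <- function(model_probs, member_mask) {
  if (length(model_probs) != length(member_mask))
    stop("mask length mismatch")
  sum(model_probs[member_mask])
}

#' Inclusion probabilities for a nested model set
#'
#' @param set an `mpt_model_set`.
#' @param model_probs posterior (or prior) model probabilities aligned
#'   with `set$models`.
#' @return named vector, one inclusion probability per candidate
#'   parameter.
#' @export
inclusion_probabilities <- function(set, model_probs) {
  vapply(rownames(set$membership), function(p)
    inclusion_probability(model_probs, set$membership[p, ]), 0)
}

#' Savage--Dickey density ratio for one difference parameter
#'
#' Log Bayes factor of the restricted model (delta = 0) against the free
#' model, estimated as the log ratio of the posterior density at zero to
#' the prior normal density at zero. The posterior density is a Gaussian
#' kernel estimate with Silverman's bandwidth; this estimator is
#' approximate and intended as a cross-check on bridge-sampling results
#' for nested comparisons.
#'
#' @param delta_draws posterior draws of one difference parameter
#'   (>= 1000 recommended).
#' @param sigma_delta prior standard deviation of the difference.
#' @return the log Bayes factor (restricted over free).
#' @export
savage_dickey <- function(delta_draws, sigma_delta) {
  delta_draws <- delta_draws[is.finite(delta_draws)]
  if (length(delta_draws) < 2L || stats::sd(delta_draws) == 0)
    stop("degenerate draws")
  h <- stats::bw.nrd0(delta_draws)
  post0 <- mean(stats::dnorm(0, delta_draws, h))
  log(post0) - stats::dnorm(0, 0, sigma_delta, log = TRUE)
}

#' Savage--Dickey posterior model probabilities for a nested family
#'
#' From draws of the full model's difference parameters alone: for each
#' model in the family, the Bayes factor against the full model is the
#' joint posterior density of its fixed subset at zero (product-kernel
#' Gaussian estimate, Silverman's rule per dimension) over the joint
#' prior density at zero. Softmaxing these log Bayes factors with the
#' prior model probabilities gives the posterior model probabilities.
#'
#' @param delta_draws matrix of posterior draws of the full model's
#'   difference parameters (columns named after the candidates).
#' @param set an `mpt_model_set` from [enumerate_nested_models()].
#' @param sigma_delta prior standard deviation of each difference.
#' @return named probability vector over the models of `set`.
#' @export
savage_dickey_model_probs <- function(delta_draws, set, sigma_delta) {
  delta_draws <- as.matrix(delta_draws)
  cand <- rownames(set$membership)
  if (!all(cand %in% colnames(delta_draws)))
    stop("delta_draws must have one column per candidate parameter")
  n <- nrow(delta_draws)
  log_bf_vs_full <- vapply(seq_along(set$models), function(m) {
    fixed <- cand[!set$membership[, m]]
    if (!length(fixed)) return(0)
    x <- delta_draws[, fixed, drop = FALSE]
    q <- ncol(x)
    h <- apply(x, 2, stats::sd) * (4 / ((q + 2) * n))^(1 / (q + 4))
    kern <- matrix(stats::dnorm(0, x, rep(h, each = n)), n, q)
    post0 <- mean(apply(kern, 1, prod))
    log(post0) - q * stats::dnorm(0, 0, sigma_delta, log = TRUE)
  }, 0)
  stats::setNames(
    posterior_model_probabilities(log_bf_vs_full, set$prior_probs),
    set$labels)
}

#' Full nested model comparison by bridge sampling
#'
#' Fits every model of a nested family, bridges each, and assembles
#' posterior model probabilities and inclusion probabilities. Summary
#' probabilities use the median log marginal likelihood across bridge
#' repetitions.
#'
#' @param set an `mpt_model_set`.
#' @param data an `mpt_counts` object (two conditions).
#' @param seed master seed; fitting and bridging of each model derive
#'   their seeds from it.
#' @param method bridge variant, see [bridge_sampler()].
#' @param n_repetitions bridge repetitions per model.
#' @param ... chain settings passed to [sample_posterior()].
#' @return an object of class `mpt_comparison`: per-model log ML
#'   summaries, posterior model probabilities, prior and posterior
#'   inclusion probabilities, and per-model diagnostics (max R-hat).
#' @export
compare_nested_models <- function(set, data, seed = 1L, method = "warp3",
                                  n_repetitions = 1L, ...) {
  M <- length(set$models)
  seeds <- derive_seeds(seed, 2L * M)
  log_mls <- numeric(M)
  ranges <- matrix(NA_real_, M, 2)
  max_rhat <- numeric(M)
  fits <- vector("list", M)
  for (m in seq_len(M)) {
    ch <- sample_posterior(set$models[[m]], data, seed = seeds[m], ...)
    max_rhat[m] <- max(rhat(ch))
    br <- estimate_log_ml(set$models[[m]], data, ch, method = method,
                          n_repetitions = n_repetitions,
                          seed = seeds[M + m])
    log_mls[m] <- br$log_ml
    ranges[m, ] <- br$range
    fits[[m]] <- list(chains = ch, bridge = br)
  }
  pmp <- posterior_model_probabilities(log_mls, set$prior_probs)
  structure(
    list(labels = set$labels, log_mls = stats::setNames(log_mls, set$labels),
         log_ml_ranges = ranges,
         pmp = stats::setNames(pmp, set$labels),
         prior_inclusion = inclusion_probabilities(set, set$prior_probs),
         posterior_inclusion = inclusion_probabilities(set, pmp),
         max_rhat = max_rhat, method = method, seed = seed, fits = fits),
    class = "mpt_comparison")
}

#' @export
print.mpt_comparison <- function(x, ...) {
  cat("Nested model comparison (", x$method, "):\n", sep = "")
  df <- data.frame(model = x$labels,
                   log_ml = round(x$log_mls, 3),
                   pmp = round(x$pmp, 4),
                   max_rhat = round(x$max_rhat, 3))
  print(df, row.names = FALSE)
  cat("posterior inclusion probabilities:\n")
  print(round(x$posterior_inclusion, 4))
  invisible(x)
}

#' Write a comparison report
#'
#' JSON (and optional CSV) with per-model log marginal likelihood
#' summaries, posterior model probabilities, and per-parameter
#' prior/posterior inclusion probabilities.
#'
#' @param x an `mpt_comparison`.
#' @param file path to the JSON report.
#' @param csv optional path for a per-model CSV table.
#' @export
write_comparison <- function(x, file, csv = NULL) {
  if (!requireNamespace("jsonlite", quietly = TRUE))
    stop("jsonlite is required to write JSON results")
  obj <- list(
    method = x$method, seed = x$seed,
    models = lapply(seq_along(x$labels), function(m)
      list(label = x$labels[m], log_ml = unname(x$log_mls[m]),
           log_ml_min = x$log_ml_ranges[m, 1],
           log_ml_max = x$log_ml_ranges[m, 2],
           pmp = unname(x$pmp[m]), max_rhat = x$max_rhat[m])),
    prior_inclusion = as.list(x$prior_inclusion),
    posterior_inclusion = as.list(x$posterior_inclusion))
  jsonlite::write_json(obj, file, auto_unbox = TRUE, digits = NA)
  if (!is.null(csv)) {
    utils::write.csv(data.frame(model = x$labels, log_ml = x$log_mls,
                                pmp = x$pmp, max_rhat = x$max_rhat),
                     csv, row.names = FALSE)
  }
  invisible(file)
}
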