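#' Generate a latent-trait MPT dataset with known ground truth
#'
#' Simulates the full generative chain: unscaled random effects
#' `omega_i ~ N_P(0, Q)`, probit-scale participant parameters
#' `theta'_i = mu + sign_c * delta/1 + xi * omega_i` per condition (the
#' condition signs are -1/2 and +1/2 as in the model), and
#' product-multinomial counts per subtree with `J_k` items. Defaults for
#' the fixture truths are configuration choices on the probability scale
#' (means in the 0.3--0.7 band, scales 0.4--1.0), not claims about any
#' real dataset.
#'
#' @param model an `lt_model`.
#' @param truth list with `mu` (probit-scale group means, length P),
#'   `xi` (positive scales, length P), optional `Q` (P x P correlation
#'   matrix of the unscaled effects, default identity), and optional
#'   `delta` (length P, used only at free positions).
#' @param I number of participants.
#' @param J items per subtree (length K, or a single value recycled).
#' @param seed integer seed; identical seeds give identical counts.
#' @return list with `data` (an `mpt_counts`) and `truth` (inputs plus
#'   the realized `omega` and per-participant `theta`, and the seed).
#' @export
generate_dataset <- function(model, truth, I, J, seed = 1L) {
  stopifnot(inherits(model, "lt_model"))
  spec <- model$spec
  P <- model$P
  K <- length(spec$tree_labels)
  J <- as.integer(rep(J, length.out = K))
  if (any(J < 1L)) stop("J must be >= 1 per subtree")
  mu <- align_param_vec(rep(truth$mu, length.out = P), spec$params)
  xi <- align_param_vec(rep(truth$xi, length.out = P), spec$params)
  Q <- truth$Q %||% diag(P)
  ch <- try(chol(Q), silent = TRUE)
  if (inherits(ch, "try-error"))
    stop("truth covariance Q is not positive definite")
  delta <- align_param_vec(rep(truth$delta %||% numeric(P),
                               length.out = P), spec$params)
  delta <- embed_delta(model, delta[model$delta_free])

  set.seed(seed)
  omega <- matrix(stats::rnorm(I * P), I, P) %*% ch
  ncat <- length(spec$cat_labels)
  counts <- array(0L, c(I, ncat, model$n_cond))
  theta <- array(NA_real_, c(I, P, model$n_cond),
                 dimnames = list(NULL, spec$params, NULL))
  for (cc in seq_len(model$n_cond)) {
    s <- model$cond_signs[cc]
    for (i in seq_len(I)) {
      th <- stats::pnorm(mu + s * delta + xi * omega[i, ])
      theta[i, , cc] <- th
      cp <- category_probabilities(spec, th)
      for (k in seq_len(K)) {
        idx <- which(spec$cat_tree == k)
        counts[i, idx, cc] <- stats::rmultinom(1, J[k], cp[[k]])
      }
    }
  }
  list(data = mpt_counts(counts, spec),
       truth = list(mu = mu, xi = xi, Q = Q, delta = delta,
                    Sigma = diag(xi) %*% Q %*% diag(xi),
                    omega = omega, theta = theta, seed = seed))
}

#' Pair-clustering fixture
#'
#' The classic storage--retrieval MPT for free recall of semantically
#' related word pairs plus singletons: parameters `c` (cluster storage),
#' `r` (cluster retrieval), `u` (storage-retrieval of unclustered
#' words), and `a` (singleton storage-retrieval) with the usual
#' constraint `a = u`, so P = 3 free parameters. Word pairs are scored
#' into four categories (both recalled adjacently / both non-adjacently
#' / one / neither), singletons into two (recalled / not). The fixture
#' uses a two-condition (trial 1 vs trial 2) difference design with all
#' three deltas as candidates, 21 participants, and 20 word pairs; the
#' singleton item count is configuration (default 10).
#'
#' The default generating truth has `r` and `u` increasing between
#' conditions and `c` stable.
#'
#' @param I participants (default 21).
#' @param J_pairs word pairs (default 20).
#' @param J_singletons singletons (default 10).
#' @param delta_prior passed to [latent_trait_model()].
#' @return list with `spec` (`mpt_model`), `model` (`lt_model`, two
#'   conditions, all deltas free), `truth` (default generating values),
#'   `I`, `J`, and `candidates`.
#' @export
pair_clustering_fixture <- function(I = 21L, J_pairs = 20L,
                                    J_singletons = 10L,
                                    delta_prior = "medium") {
  spec <- parse_eqn(pair_clustering_eqn(), name = "pair_clustering",
                    constraints = c(a = "u"))
  model <- latent_trait_model(spec, n_cond = 2L,
                              delta_free = c("c", "r", "u"),
                              delta_prior = delta_prior)
  truth <- list(mu = stats::qnorm(c(c = 0.45, r = 0.40, u = 0.55)),
                xi = c(c = 0.6, r = 0.8, u = 0.5),
                Q = diag(3),
                delta = c(c = 0, r = 0.8, u = 0.5))
  list(spec = spec, model = model, truth = truth, I = as.integer(I),
       J = c(pairs = as.integer(J_pairs),
             singletons = as.integer(J_singletons)),
       candidates = c("c", "r", "u"))
}

#' @rdname pair_clustering_fixture
#' @export
pair_clustering_eqn <- function() {
"# pair-clustering MPT: word-pair subtree (4 categories) + singletons (2)
pairs E1 c*r
pairs E2 (1-c)*u*u
pairs E3 (1-c)*u*(1-u)
pairs E3 (1-c)*(1-u)*u
pairs E4 c*(1-r)
pairs E4 (1-c)*(1-u)*(1-u)
singletons F1 a
singletons F2 (1-a)
"
}

#' Illusory-truth fixture: knowledge- vs fluency-conditional MPTs
#'
#' Two non-nested 5-parameter MPTs for true/false judgments of
#' statements in a 2 (truth status) x 2 (assumed knowledge) x 2
#' (repetition) design. Both models share the parameters `kk`, `ku`
#' (knowledge retrieval for known/unknown statements), `fr`, `fn`
#' (fluency for repeated/new statements), and `g` (guessing "true",
#' shared across replicates). The two base subtrees (true and false
#' statements) are replicated four times -- known/new, known/repeated,
#' unknown/new, unknown/repeated -- giving eight subtrees of two
#' categories each.
#'
#' The knowledge-conditional tree consults knowledge first and falls
#' back on fluency; the fluency-conditional tree relies on fluency first
#' and consults knowledge only in its absence. The trees coincide when
#' fluency never drives the response (f = 0), and their true-statement
#' subtrees coincide under certain knowledge retrieval (k = 1). The
#' guessing parameter receives a full latent-trait random effect like
#' every other parameter.
#'
#' @param I participants (default 39).
#' @param J items per design cell (default 22).
#' @return list with `kc_spec`, `fc_spec` (`mpt_model`s), matching
#'   `kc_model`/`fc_model` (`lt_model`s, one condition), a default
#'   generating `truth`, `I`, and `J`.
#' @export
truth_effect_fixture <- function(I = 39L, J = 22L) {
  kc <- parse_eqn(truth_effect_eqn("knowledge"),
                  name = "knowledge_conditional")
  fc <- parse_eqn(truth_effect_eqn("fluency"),
                  name = "fluency_conditional")
  truth <- list(mu = stats::qnorm(c(kk = 0.65, ku = 0.30, fr = 0.55,
                                    fn = 0.35, g = 0.5)),
                xi = c(kk = 0.6, ku = 0.6, fr = 0.6, fn = 0.6, g = 0.4),
                Q = diag(5))
  list(kc_spec = kc, fc_spec = fc,
       kc_model = latent_trait_model(kc),
       fc_model = latent_trait_model(fc),
       truth = truth, I = as.integer(I), J = as.integer(J))
}

# truth vectors may be named; reorder to the spec's parameter order
align_param_vec <- function(x, params) {
  if (!is.null(names(x)) && all(params %in% names(x))) x <- x[params]
  unname(x)
}

# EQN text for the eight-subtree truth-effect models; replicates are
# (knowledge status, repetition) cells, each with a true-statement and a
# false-statement subtree scored as "true"/"false" responses
truth_effect_eqn <- function(type = c("knowledge", "fluency")) {
  type <- match.arg(type)
  cells <- list(c("kn_new", "kk", "fn"), c("kn_rep", "kk", "fr"),
                c("un_new", "ku", "fn"), c("un_rep", "ku", "fr"))
  lines <- character(0)
  for (cell in cells) {
    lab <- cell[1]; k <- cell[2]; f <- cell[3]
    tt <- paste0(lab, "_true")   # true statements
    tf <- paste0(lab, "_false")  # false statements
    if (type == "knowledge") {
      lines <- c(lines,
        paste(tt, "true", k),
        paste(tt, "true", sprintf("(1-%s)*%s", k, f)),
        paste(tt, "true", sprintf("(1-%s)*(1-%s)*g", k, f)),
        paste(tt, "false", sprintf("(1-%s)*(1-%s)*(1-g)", k, f)),
        paste(tf, "true", sprintf("(1-%s)*%s", k, f)),
        paste(tf, "true", sprintf("(1-%s)*(1-%s)*g", k, f)),
        paste(tf, "false", k),
        paste(tf, "false", sprintf("(1-%s)*(1-%s)*(1-g)", k, f)))
    } else {
      lines <- c(lines,
        paste(tt, "true", f),
        paste(tt, "true", sprintf("(1-%s)*%s", f, k)),
        paste(tt, "true", sprintf("(1-%s)*(1-%s)*g", f, k)),
        paste(tt, "false", sprintf("(1-%s)*(1-%s)*(1-g)", f, k)),
        paste(tf, "true", f),
        paste(tf, "true", sprintf("(1-%s)*(1-%s)*g", f, k)),
        paste(tf, "false", sprintf("(1-%s)*%s", f, k)),
        paste(tf, "false", sprintf("(1-%s)*(1-%s)*(1-g)", f, k)))
    }
  }
  paste(lines, collapse = "\n")
}
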