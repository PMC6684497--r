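#' Parse an EQN-style MPT model description
#'
#' Reads the community EQN dialect for multinomial processing tree (MPT)
#' models: one line per branch, giving a subtree label, a response-category
#' label, and a product of factors of the form `p` or `(1-p)` separated by
#' `*`. Multiple lines for the same (subtree, category) pair accumulate as
#' additional branches whose probabilities are summed. `#` starts a comment;
#' an optional leading line holding a single integer (the conventional line
#' count) is ignored. Tokens may be separated by whitespace or semicolons.
#'
#' Subtrees, categories, and parameters are indexed by first appearance;
#' file labels are preserved verbatim for reporting.
#'
#' @param text character: either the EQN content (possibly a multi-line
#'   string) or a vector of lines.
#' @param name model name stored in the result.
#' @param constraints optional named character vector of equality
#'   constraints, e.g. `c(a = "u")` replaces parameter `a` by `u` everywhere
#'   and removes it from the free parameter list.
#' @return an object of class `mpt_model` with elements `params` (free
#'   parameter names, length P), `tree_labels`, `cat_labels`, `cat_tree`
#'   (subtree index of each category), exponent matrices `V` and `W`
#'   (branches x P), and `branch_cat` (category index of each branch).
#' @examples
#' m <- parse_eqn("
#'   1 11 c*r
#'   1 12 (1-c)*u*u
#'   1 13 (1-c)*u*(1-u)
#'   1 13 (1-c)*(1-u)*u
#'   1 14 c*(1-r)
#'   1 14 (1-c)*(1-u)*(1-u)
#'   2 21 a
#'   2 22 (1-a)", constraints = c(a = "u"))
#' category_probabilities(m, c(c = 0.5, r = 0.5, u = 0.5))
#' @export
parse_eqn <- function(text, name = "mpt", constraints = NULL) {
  if (length(text) == 1L) text <- strsplit(text, "\n", fixed = TRUE)[[1]]
  text <- sub("#.*$", "", text)
  text <- trimws(text)
  text <- text[nzchar(text)]
  if (!length(text)) stop("empty EQN input")

  # conventional leading branch count: a first line with one integer token
  if (length(text) > 1L && grepl("^[0-9]+$", text[1])) text <- text[-1]
  if (!length(text)) stop("EQN input contains no branch lines")

  tree_lab <- character(0)
  cat_lab <- character(0)
  cat_tree <- integer(0)
  branch_cat <- integer(0)
  factors <- list()          # per branch: list of (param, complement)
  param_lab <- character(0)

  for (line in text) {
    tok <- strsplit(line, "[;[:space:]]+")[[1]]
    tok <- tok[nzchar(tok)]
    if (length(tok) < 3L)
      stop("malformed EQN line (need subtree, category, branch): ", line)
    tr <- tok[1]
    ct <- tok[2]
    expr <- gsub("[[:space:]]", "", paste(tok[-(1:2)], collapse = ""))

    ti <- match(tr, tree_lab)
    if (is.na(ti)) {
      tree_lab <- c(tree_lab, tr)
      ti <- length(tree_lab)
    }
    ci <- which(cat_lab == ct & cat_tree == ti)
    if (!length(ci)) {
      cat_lab <- c(cat_lab, ct)
      cat_tree <- c(cat_tree, ti)
      ci <- length(cat_lab)
    }

    fac <- strsplit(expr, "*", fixed = TRUE)[[1]]
    fac <- fac[nzchar(fac)]
    if (!length(fac)) stop("empty branch expression in line: ", line)
    parsed <- lapply(fac, function(f) {
      if (grepl("^\\(1-[A-Za-z][A-Za-z0-9_.]*\\)$", f)) {
        list(param = sub("^\\(1-([^)]*)\\)$", "\\1", f), comp = TRUE)
      } else if (grepl("^[A-Za-z][A-Za-z0-9_.]*$", f)) {
        list(param = f, comp = FALSE)
      } else {
        stop("malformed factor token '", f, "' in line: ", line)
      }
    })
    for (pf in parsed) {
      if (!pf$param %in% param_lab) param_lab <- c(param_lab, pf$param)
    }
    branch_cat <- c(branch_cat, ci)
    factors[[length(factors) + 1L]] <- parsed
  }

  P <- length(param_lab)
  B <- length(factors)
  V <- matrix(0L, B, P, dimnames = list(NULL, param_lab))
  W <- matrix(0L, B, P, dimnames = list(NULL, param_lab))
  for (b in seq_len(B)) {
    for (pf in factors[[b]]) {
      j <- match(pf$param, param_lab)
      if (pf$comp) W[b, j] <- W[b, j] + 1L else V[b, j] <- V[b, j] + 1L
    }
  }

  model <- structure(
    list(name = name, params = param_lab,
         tree_labels = tree_lab, cat_labels = cat_lab,
         cat_tree = cat_tree, branch_cat = branch_cat,
         V = V, W = W, constraints = NULL),
    class = "mpt_model")
  if (!is.null(constraints)) model <- apply_constraints(model, constraints)
  validate_mpt_model(model)
  model
}

#' @export
print.mpt_model <- function(x, ...) {
  K <- length(x$tree_labels)
  cat("MPT model '", x$name, "': P = ", length(x$params),
      " (", paste(x$params, collapse = ", "), "), K = ", K,
      " subtrees\n", sep = "")
  for (k in seq_len(K)) {
    cats <- which(x$cat_tree == k)
    cat("  subtree ", x$tree_labels[k], ": L = ", length(cats),
        " categories (", paste(x$cat_labels[cats], collapse = ", "),
        ")\n", sep = "")
  }
  if (!is.null(x$constraints)) {
    cat("  constraints:",
        paste(names(x$constraints), "=", x$constraints, collapse = ", "),
        "\n")
  }
  invisible(x)
}

validate_mpt_model <- function(m) {
  stopifnot(length(m$cat_tree) == length(m$cat_labels),
            nrow(m$V) == length(m$branch_cat),
            identical(dim(m$V), dim(m$W)))
  if (any(tabulate(m$cat_tree, length(m$tree_labels)) < 1L))
    stop("every subtree needs at least one category")
  if (any(tabulate(m$branch_cat, length(m$cat_labels)) < 1L))
    stop("every category needs at least one branch")
  invisible(m)
}

# equality constraints (e.g. a = u): fold the constrained parameter's
# exponents onto its target and drop it, so P counts only free parameters
apply_constraints <- function(model, constraints) {
  stopifnot(is.character(constraints), !is.null(names(constraints)))
  for (from in names(constraints)) {
    to <- constraints[[from]]
    jf <- match(from, model$params)
    jt <- match(to, model$params)
    if (is.na(jf)) stop("constraint source '", from, "' not in model")
    if (is.na(jt)) stop("constraint target '", to, "' not in model")
    model$V[, jt] <- model$V[, jt] + model$V[, jf]
    model$W[, jt] <- model$W[, jt] + model$W[, jf]
    model$V <- model$V[, -jf, drop = FALSE]
    model$W <- model$W[, -jf, drop = FALSE]
    model$params <- model$params[-jf]
  }
  model$constraints <- c(model$constraints, constraints)
  model
}

#' Probability of a single MPT branch
#'
#' Traversing the tree from root to leaf multiplies the probabilities of the
#' processes encountered: the branch probability is
#' \eqn{\prod_p \theta_p^{v_p} (1-\theta_p)^{w_p}}.
#'
#' @param model an `mpt_model`.
#' @param branch integer branch index (row of the exponent matrices).
#' @param theta probability vector of length P (values in \[0, 1\]).
#' @return the branch probability, in \[0, 1\].
#' @export
branch_probability <- function(model, branch, theta) {
  theta <- check_theta(model, theta)
  if (!(is.numeric(branch) && length(branch) == 1L &&
        branch >= 1 && branch <= nrow(model$V)))
    stop("unknown branch reference: ", branch)
  v <- model$V[branch, ]
  w <- model$W[branch, ]
  prod(theta^v) * prod((1 - theta)^w)
}

check_theta <- function(model, theta) {
  P <- length(model$params)
  if (length(theta) != P)
    stop("theta must have length ", P, " (one per free parameter)")
  if (!is.null(names(theta))) theta <- theta[model$params]
  if (anyNA(theta) || any(theta < 0 | theta > 1))
    stop("theta components must lie in [0, 1]")
  unname(theta)
}

#' Category probabilities of an MPT model
#'
#' Sums branch probabilities within each response category. For any
#' parameter vector strictly inside the unit cube, each subtree's category
#' probabilities sum to one.
#'
#' @inheritParams branch_probability
#' @return a named list, one numeric vector of category probabilities per
#'   subtree.
#' @export
category_probabilities <- function(model, theta) {
  theta <- check_theta(model, theta)
  bp <- exp(model$V %*% log(pmax(theta, 0)) +
              model$W %*% log(pmax(1 - theta, 0)))
  # 0^0 handling: log(0) * 0 exponent never occurs because V,W are >= 0
  # integer counts -- recompute exactly where theta hits the boundary
  if (any(theta == 0 | theta == 1)) {
    bp <- vapply(seq_len(nrow(model$V)), function(b)
      prod(theta^model$V[b, ]) * prod((1 - theta)^model$W[b, ]), 0)
  }
  catp <- as.vector(rowsum(as.vector(bp), model$branch_cat,
                           reorder = TRUE))
  out <- split(catp, model$cat_tree)
  names(out) <- model$tree_labels
  for (k in seq_along(out))
    names(out[[k]]) <- model$cat_labels[model$cat_tree == k]
  out
}

#' Product-multinomial log-likelihood for one participant
#'
#' The observed category frequencies of each subtree follow an independent
#' multinomial with `J_k` trials; the joint probability is their product.
#' Multinomial coefficients are included (via log-gamma, safe for large
#' `J_k`). A zero category probability paired with a positive count gives
#' `-Inf`, never `NaN`.
#'
#' @inheritParams branch_probability
#' @param counts integer vector of category counts in global category order
#'   (as in `model$cat_labels`).
#' @return the log-probability (<= 0).
#' @export
log_likelihood <- function(model, counts, theta) {
  ncat <- length(model$cat_labels)
  if (length(counts) != ncat)
    stop("counts must have one entry per category (", ncat, ")")
  if (any(counts < 0)) stop("counts must be non-negative")
  p <- unlist(category_probabilities(model, theta), use.names = FALSE)
  # category_probabilities returns categories grouped by subtree in global
  # order because cat_tree is non-decreasing within first-appearance order;
  # restore global order explicitly to be safe
  ord <- order(model$cat_tree, seq_along(model$cat_tree))
  p[ord] <- p
  ll <- 0
  for (k in seq_along(model$tree_labels)) {
    idx <- which(model$cat_tree == k)
    n <- counts[idx]
    pk <- p[idx]
    ll <- ll + lgamma(sum(n) + 1) - sum(lgamma(n + 1))
    pos <- n > 0
    if (any(pk[pos] <= 0)) return(-Inf)
    ll <- ll + sum(n[pos] * log(pk[pos]))
  }
  ll
}
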