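#' Participant-level category count table
#'
#' Holds per-participant, per-subtree, per-category response frequencies,
#' optionally for one or two experimental conditions, with fixed item
#' totals `J_k` per subtree (responses are aggregated over items but not
#' over participants).
#'
#' @param counts an I x ncat integer matrix (single condition) or an
#'   I x ncat x ncond array, categories in the model's global order.
#' @param model the `mpt_model` the counts belong to.
#' @return an object of class `mpt_counts` with elements `counts` (always
#'   an I x ncat x ncond array), `I`, `J` (items per subtree), `n_cond`.
#' @export
mpt_counts <- function(counts, model) {
  if (length(dim(counts)) == 2L)
    counts <- array(counts, c(nrow(counts), ncol(counts), 1L))
  ncat <- length(model$cat_labels)
  if (dim(counts)[2] != ncat)
    stop("counts must have ", ncat, " category columns")
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers")
  I <- dim(counts)[1]
  if (I < 1L) stop("need at least one participant")
  n_cond <- dim(counts)[3]
  K <- length(model$tree_labels)
  J <- integer(K)
  for (k in seq_len(K)) {
    idx <- which(model$cat_tree == k)
    tots <- apply(counts[, idx, , drop = FALSE], c(1, 3), sum)
    if (length(unique(as.vector(tots))) != 1L)
      stop("item totals J_", k, " differ across participants/conditions")
    J[k] <- tots[1]
  }
  structure(list(counts = counts, I = I, J = J, n_cond = n_cond,
                 cat_labels = model$cat_labels, cat_tree = model$cat_tree,
                 tree_labels = model$tree_labels),
            class = "mpt_counts")
}

#' @export
print.mpt_counts <- function(x, ...) {
  cat("MPT count table: I =", x$I, "participants,",
      length(x$J), "subtrees (J =", paste(x$J, collapse = ", "),
      "),", x$n_cond, "condition(s)\n")
  invisible(x)
}

#' Read / write count tables as CSV
#'
#' One row per participant (and per condition when there are several), one
#' integer column per (subtree, category) pair named
#' `"treeLabel.categoryLabel"`. An optional `id` column and, for
#' multi-condition data, a `condition` column are recognized.
#'
#' @param file path to a CSV file.
#' @param model the `mpt_model` defining the category layout.
#' @return `read_counts` returns an `mpt_counts` object.
#' @export
read_counts <- function(file, model) {
  df <- utils::read.csv(file, check.names = FALSE)
  cond <- if ("condition" %in% names(df)) df$condition else rep(1L, nrow(df))
  df <- df[, setdiff(names(df), c("id", "condition")), drop = FALSE]
  want <- paste(model$tree_labels[model$cat_tree], model$cat_labels,
                sep = ".")
  if (!all(want %in% names(df)))
    stop("missing count columns: ",
         paste(setdiff(want, names(df)), collapse = ", "))
  m <- as.matrix(df[, want])
  conds <- sort(unique(cond))
  I <- sum(cond == conds[1])
  arr <- array(0L, c(I, ncol(m), length(conds)))
  for (ci in seq_along(conds)) arr[, , ci] <- m[cond == conds[ci], ]
  mpt_counts(arr, model)
}

#' @rdname read_counts
#' @param data an `mpt_counts` object.
#' @export
write_counts <- function(data, file, model) {
  cols <- paste(model$tree_labels[model$cat_tree], model$cat_labels,
                sep = ".")
  rows <- do.call(rbind, lapply(seq_len(data$n_cond), function(ci) {
    df <- as.data.frame(data$counts[, , ci, drop = FALSE][, , 1])
    names(df) <- cols
    cbind(id = seq_len(data$I), condition = ci, df)
  }))
  if (data$n_cond == 1L) rows$condition <- NULL
  utils::write.csv(rows, file, row.names = FALSE, quote = FALSE)
  invisible(file)
}
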