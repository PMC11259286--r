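#' Individual sort co-occurrence matrix
#'
#' The binary S x S matrix of one sorter: entry (i, j) is 1 when statements
#' i and j share a pile (the diagonal is all 1). Because a sort is a
#' partition, each matrix is a block-diagonal pattern of 1s up to row
#' ordering, i.e. an equivalence relation.
#'
#' @param sort a `cm_sort` record.
#' @param statements `cm_statements` giving the row/column order.
#' @return integer S x S 0/1 matrix with statement IDs as dimnames.
#' @export
individual_matrix <- function(sort, statements) {
  validate_sort(sort, statements)
  ids <- statements$statement_id
  S <- length(ids)
  m <- matrix(0L, S, S, dimnames = list(ids, ids))
  for (p in sort$piles) {
    idx <- match(p$members, ids)
    m[idx, idx] <- 1L
  }
  m
}

#' Aggregate similarity matrix across sorters
#'
#' Element-wise sum of the individual binary co-occurrence matrices: entry
#' (i, j) counts how many of the N sorters placed i and j in the same pile.
#' Values range from 0 to N and the diagonal equals N.
#'
#' @param x a `cm_sorts` collection, or a list of binary matrices sharing
#'   one statement ordering.
#' @param statements `cm_statements`; required when `x` is a `cm_sorts`.
#' @return `cm_similarity`: an integer matrix with attributes `n_sorters`
#'   and `statement_ids`.
#' @export
aggregate_similarity <- function(x, statements = NULL) {
  if (inherits(x, "cm_sorts") || (is.list(x) && length(x) && inherits(x[[1]], "cm_sort"))) {
    if (is.null(statements)) cm_abort("statements required to aggregate sorts")
    x <- lapply(x, individual_matrix, statements = statements)
  }
  if (!length(x)) cm_abort("no sort matrices to aggregate")
  dims <- vapply(x, function(m) dim(m), integer(2))
  if (any(dims != dims[1, 1]))
    cm_abort("sort matrices differ in dimension")
  vals <- Reduce(`+`, x)
  ids <- as.integer(rownames(vals) %||% seq_len(nrow(vals)))
  structure(vals, n_sorters = length(x), statement_ids = ids,
            class = c("cm_similarity", class(vals)))
}

#' @export
print.cm_similarity <- function(x, ...) {
  cat(sprintf("Aggregate similarity: %d statements, %d sorters, off-diagonal range %d..%d\n",
              nrow(x), attr(x, "n_sorters"),
              min(x[row(x) != col(x)]), max(x[row(x) != col(x)])))
  invisible(x)
}

#' Dissimilarities for ordination
#'
#' Converts co-occurrence counts to dissimilarities: `count_complement`
#' gives `N - s_ij` (the classical concept-mapping convention) and
#' `proportion_complement` gives `1 - s_ij / N`. Nonmetric scaling depends
#' only on the rank order of dissimilarities, so the two transforms produce
#' identical configurations and stress.
#'
#' @param sim `cm_similarity`.
#' @param transform `"count_complement"` or `"proportion_complement"`.
#' @return `cm_dissimilarity`: numeric matrix with zero diagonal and
#'   attributes `transform`, `n_sorters`, `statement_ids`.
#' @export
to_dissimilarity <- function(sim,
                             transform = c("count_complement",
                                           "proportion_complement")) {
  transform <- match.arg(transform)
  N <- attr(sim, "n_sorters")
  if (is.null(N) || N == 0) cm_abort("similarity matrix has no sorters (N = 0)")
  d <- if (transform == "count_complement") N - unclass(sim)
       else 1 - unclass(sim) / N
  d <- (d + t(d)) / 2
  diag(d) <- 0
  structure(d, transform = transform, n_sorters = N,
            statement_ids = attr(sim, "statement_ids"),
            class = c("cm_dissimilarity", "matrix", "array"))
}

# accept cm_dissimilarity / dist / plain symmetric matrix
as_dissim_matrix <- function(d) {
  if (inherits(d, "dist")) d <- as.matrix(d)
  if (!is.matrix(d) || nrow(d) != ncol(d))
    cm_abort("dissimilarity must be a square matrix or dist object")
  unclass(d)
}
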