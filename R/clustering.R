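#' Ward hierarchical clustering of the point map
#'
#' Agglomerates the statements on their (canonicalized) 2-D map coordinates
#' with Ward's minimum-variance criterion: each merge is the pair of
#' clusters whose union least increases the total within-cluster sum of
#' squared Euclidean distances to centroids (delta-ESS). The clustering
#' operates on the map, not on the raw similarity matrix. Merge heights are
#' reported as delta-ESS and are non-decreasing (Ward on Euclidean
#' distances has no inversions).
#'
#' @param coordinates S x 2 matrix or a `cm_pointmap`.
#' @param linkage `"ward"` (default, the canonical concept-mapping choice),
#'   `"complete"` or `"average"` for sensitivity analysis.
#' @return `cm_tree`: list with the underlying `hclust` object, `heights`
#'   (delta-ESS for ward, linkage heights otherwise), and `statement_ids`.
#' @export
ward_tree <- function(coordinates, linkage = c("ward", "complete", "average")) {
  linkage <- match.arg(linkage)
  if (inherits(coordinates, "cm_pointmap")) coordinates <- coordinates$coordinates
  X <- as.matrix(coordinates)
  if (nrow(X) < 2) cm_abort("need at least 2 statements to cluster")
  if (any(!is.finite(X))) cm_abort("non-finite coordinates")
  method <- switch(linkage, ward = "ward.D2", complete = "complete",
                   average = "average")
  hc <- hclust(dist(X), method = method)
  heights <- if (linkage == "ward") hc$height^2 / 2 else hc$height
  if (any(diff(heights) < -1e-8))
    cm_abort("merge-height inversion in the cluster tree",
             class = "cm_computation_error")
  ids <- as.integer(rownames(X) %||% seq_len(nrow(X)))
  structure(list(hclust = hc, heights = heights, linkage = linkage,
                 statement_ids = ids),
            class = "cm_tree")
}

#' @export
print.cm_tree <- function(x, ...) {
  cat(sprintf("%s merge tree: %d statements, %d merges, height range %.3g..%.3g\n",
              x$linkage, length(x$statement_ids), length(x$heights),
              min(x$heights), max(x$heights)))
  invisible(x)
}

#' Merge list of a cluster tree
#'
#' @param tree `cm_tree`.
#' @return data frame (merge, a, b, height, new_size) in `hclust` merge
#'   encoding (negative = leaf statement index, positive = earlier merge).
#' @export
merge_table <- function(tree) {
  m <- tree$hclust$merge
  sizes <- integer(nrow(m))
  size_of <- function(v) if (v < 0) 1L else sizes[v]
  for (i in seq_len(nrow(m)))
    sizes[i] <- size_of(m[i, 1]) + size_of(m[i, 2])
  data.frame(merge = seq_len(nrow(m)), a = m[, 1], b = m[, 2],
             height = tree$heights, new_size = sizes)
}

#' Cut a merge tree into k clusters
#'
#' Undoes the last k - 1 merges. Clusters are renumbered by the lowest
#' statement ID they contain, so solutions are comparable across runs.
#'
#' @param tree `cm_tree`.
#' @param k number of clusters, 1..S.
#' @return `cm_solution`: list with `k`, `assignment` (named integer vector,
#'   statement ID -> cluster 1..k) and `labels` (empty; see
#'   [suggest_labels()]).
#' @export
cut_tree <- function(tree, k) {
  S <- length(tree$statement_ids)
  if (!is_count(k, 1L) || k > S) cm_abort(sprintf("k must be in 1..%d", S))
  raw <- cutree(tree$hclust, k = k)
  assignment <- relabel_by_lowest_id(raw, tree$statement_ids)
  structure(list(k = as.integer(k), assignment = assignment, labels = list()),
            class = "cm_solution")
}

relabel_by_lowest_id <- function(raw, ids) {
  mins <- tapply(ids, raw, min)
  newidx <- rank(mins)                      # lowest statement ID -> cluster 1
  assignment <- as.integer(newidx[as.character(raw)])
  names(assignment) <- ids
  assignment
}

#' @export
print.cm_solution <- function(x, ...) {
  sizes <- table(x$assignment)
  cat(sprintf("Cluster solution: k = %d (sizes %s)\n", x$k,
              paste(sizes, collapse = ", ")))
  invisible(x)
}

#' Nested cluster solutions over a k range
#'
#' Cuts the same tree at each k in `k_min..k_max` and verifies the nesting
#' property: each finer solution refines the coarser one.
#'
#' @param tree `cm_tree`.
#' @param k_min,k_max cluster-count range, `1 <= k_min <= k_max <= S`.
#' @return named list of `cm_solution`, names `"k6"`, `"k7"`, ...
#' @export
solution_range <- function(tree, k_min, k_max) {
  S <- length(tree$statement_ids)
  if (!is_count(k_min, 1L) || !is_count(k_max, 1L) ||
      k_min > k_max || k_max > S)
    cm_abort(sprintf("need 1 <= k_min <= k_max <= %d", S))
  sols <- lapply(seq(k_min, k_max), function(k) cut_tree(tree, k))
  names(sols) <- paste0("k", seq(k_min, k_max))
  if (length(sols) > 1)
    for (i in seq_len(length(sols) - 1L))
      if (!is_refinement(sols[[i + 1L]], sols[[i]]))
        cm_abort("nesting violated across the solution range",
                 class = "cm_computation_error")
  sols
}

#' Does one solution refine another?
#'
#' `finer` refines `coarser` when every cluster of `finer` lies entirely
#' within one cluster of `coarser`.
#'
#' @param finer,coarser `cm_solution` objects over the same statements.
#' @return logical scalar.
#' @export
is_refinement <- function(finer, coarser) {
  if (!identical(sort(names(finer$assignment)), sort(names(coarser$assignment))))
    return(FALSE)
  co <- coarser$assignment[names(finer$assignment)]
  all(tapply(co, finer$assignment, function(v) length(unique(v))) == 1L)
}

#' Build a solution from a given membership table
#'
#' Wraps an externally specified statement-to-cluster assignment (for
#' example a published grouping) as a `cm_solution` so it can feed
#' [cluster_summary()] and [pattern_match()] without re-running the
#' sort-based pipeline.
#'
#' @param membership data frame with columns `statement_id` and `cluster`
#'   (integer codes), or a named integer vector.
#' @return `cm_solution`.
#' @export
as_solution <- function(membership) {
  if (is.data.frame(membership)) {
    v <- as.integer(membership$cluster)
    names(v) <- membership$statement_id
    membership <- v
  }
  if (is.null(names(membership))) cm_abort("membership must carry statement ids")
  ks <- sort(unique(membership))
  assignment <- match(membership, ks)
  names(assignment) <- names(membership)
  structure(list(k = length(ks), assignment = assignment, labels = list()),
            class = "cm_solution")
}
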