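#' Suggest cluster labels from participant pile titles
#'
#' For every (pile, cluster) pair, scores the pile's member set against the
#' cluster's member set with the Jaccard index |intersection| / |union|
#' (this penalizes oversized piles, unlike the overlap coefficient). Per
#' cluster, piles are ranked by score; ties break by how often the label
#' string occurs across all sorters' piles, then lexicographically, then by
#' sorter ID. Unlabeled piles (empty or whitespace titles) are excluded.
#'
#' @param solution `cm_solution`.
#' @param sorts `cm_sorts`.
#' @param top keep at most this many candidates per cluster (default all).
#' @return named list (one per cluster index) of data frames
#'   `(label, score, sorter_id)`, ranked; also stored nowhere else, so
#'   attach to the solution yourself if wanted.
#' @export
suggest_labels <- function(solution, sorts, top = Inf) {
  piles <- do.call(rbind, lapply(sorts, function(s) {
    do.call(rbind, lapply(s$piles, function(p)
      if (nzchar(trimws(p$label)))
        data.frame(sorter_id = s$sorter_id, label = p$label,
                   members = I(list(p$members)), stringsAsFactors = FALSE)))
  }))
  clusters <- split(as.integer(names(solution$assignment)), solution$assignment)
  if (is.null(piles) || !nrow(piles)) {
    warning("no labeled piles; returning empty label suggestions")
    return(lapply(clusters, function(cl)
      data.frame(label = character(), score = numeric(),
                 sorter_id = character())))
  }
  label_freq <- table(piles$label)
  out <- lapply(clusters, function(members) {
    score <- vapply(piles$members, function(p)
      length(intersect(p, members)) / length(union(p, members)), numeric(1))
    df <- data.frame(label = piles$label, score = score,
                     sorter_id = piles$sorter_id, stringsAsFactors = FALSE)
    df <- df[order(-df$score, -as.vector(label_freq[df$label]),
                   df$label, df$sorter_id), , drop = FALSE]
    rownames(df) <- NULL
    head(df, n = if (is.finite(top)) top else nrow(df))
  })
  names(out) <- seq_along(clusters)
  out
}

#' Per-statement mean importance ratings
#'
#' Arithmetic mean of the available ratings for each statement, over the
#' raters in scope. Missing ratings are handled by pairwise deletion: a
#' statement's mean uses only the raters who rated it. Full precision is
#' kept; round only at presentation ([round_half_up()]).
#'
#' @param ratings `cm_ratings`.
#' @param scope `"all"` or one of the group tags
#'   (`"consumer"`, `"provider"`, `"other"`).
#' @return data frame `(statement_id, mean, n_raters)`, one row per rated
#'   statement.
#' @export
statement_means <- function(ratings, scope = "all") {
  scope <- match.arg(scope, c("all", "consumer", "provider", "other"))
  df <- as.data.frame(ratings)
  if (scope != "all") df <- df[df$group == scope, , drop = FALSE]
  if (!nrow(df)) {
    warning(sprintf("no ratings in scope '%s'", scope))
    return(data.frame(statement_id = integer(), mean = numeric(),
                      n_raters = integer()))
  }
  agg <- tapply(df$rating, df$statement_id, mean)
  n <- tapply(df$rating, df$statement_id, length)
  out <- data.frame(statement_id = as.integer(names(agg)),
                    mean = as.numeric(agg), n_raters = as.integer(n))
  out <- out[order(out$statement_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Cluster-level importance summaries
#'
#' For each cluster: the arithmetic mean of its statements' mean ratings
#' (the bolded aggregate rating of a concept-mapping results table) and the
#' population standard deviation of those statement means (divide by the
#' number of statements). Values are kept at full precision; the print
#' method rounds half-up to 2 decimals.
#'
#' @param solution `cm_solution`.
#' @param means output of [statement_means()] (or a named numeric vector of
#'   statement means).
#' @param scope tag recorded on the result (`"all"`, `"consumer"`, ...).
#' @return `cm_cluster_summary`: data frame
#'   `(cluster, n_statements, mean, sd)` with attribute `scope` and the
#'   per-statement means as attribute `statement_means`.
#' @export
cluster_summary <- function(solution, means, scope = "all") {
  if (is.data.frame(means)) {
    v <- means$mean
    names(v) <- means$statement_id
    means <- v
  }
  if (any(means < 1 - 1e-9 | means > 5 + 1e-9))
    cm_abort("statement means must lie in [1, 5]")
  ids <- names(solution$assignment)
  missing <- ids[!(ids %in% names(means))]
  if (length(missing))
    cm_abort(sprintf("no rating mean for statement(s): %s",
                     paste(missing, collapse = ", ")))
  sm <- means[ids]
  cl <- solution$assignment
  out <- data.frame(
    cluster = sort(unique(cl)),
    n_statements = as.integer(tapply(sm, cl, length)),
    mean = as.numeric(tapply(sm, cl, mean)),
    sd = as.numeric(tapply(sm, cl, pop_sd)))
  rownames(out) <- NULL
  structure(out, scope = scope, statement_means = sm,
            class = c("cm_cluster_summary", "data.frame"))
}

#' @export
print.cm_cluster_summary <- function(x, digits = 2, ...) {
  cat(sprintf("Cluster importance summary (scope: %s)\n", attr(x, "scope")))
  shown <- as.data.frame(x)
  shown$mean <- round_half_up(shown$mean, digits)
  shown$sd <- round_half_up(shown$sd, digits)
  print.data.frame(shown, row.names = FALSE)
  invisible(x)
}

#' Pattern match between two rater groups
#'
#' Compares cluster-level mean importance between two summaries of the same
#' cluster solution (e.g. consumers vs providers): per-group mean vectors,
#' their Pearson correlation (Spearman behind a flag), the descending
#' importance ordering of each group, and for each k the number of clusters
#' shared by the two groups' top-k sets.
#'
#' @param summary_a,summary_b `cm_cluster_summary` objects over identical
#'   cluster sets.
#' @param method `"pearson"` (conventional) or `"spearman"`.
#' @return `cm_pattern_match`: list with `clusters`, `mean_a`, `mean_b`,
#'   `scope_a`, `scope_b`, `correlation`, `order_a`, `order_b`
#'   (cluster indices, most important first) and `top_k_overlap`.
#' @export
pattern_match <- function(summary_a, summary_b,
                          method = c("pearson", "spearman")) {
  method <- match.arg(method)
  if (!identical(summary_a$cluster, summary_b$cluster))
    cm_abort("summaries cover different cluster sets")
  K <- nrow(summary_a)
  va <- summary_a$mean
  vb <- summary_b$mean
  order_a <- summary_a$cluster[order(-va, summary_a$cluster)]
  order_b <- summary_b$cluster[order(-vb, summary_b$cluster)]
  overlap <- vapply(seq_len(K), function(k)
    length(intersect(order_a[seq_len(k)], order_b[seq_len(k)])), integer(1))
  structure(list(clusters = summary_a$cluster,
                 mean_a = va, mean_b = vb,
                 scope_a = attr(summary_a, "scope"),
                 scope_b = attr(summary_b, "scope"),
                 correlation = cor(va, vb, method = method),
                 method = method,
                 order_a = order_a, order_b = order_b,
                 top_k_overlap = overlap),
            class = "cm_pattern_match")
}

#' @export
print.cm_pattern_match <- function(x, ...) {
  cat(sprintf("Pattern match %s vs %s: r = %.3f (%s)\n",
              x$scope_a, x$scope_b, x$correlation, x$method))
  cat(sprintf("  %s ordering: %s\n", x$scope_a, paste(x$order_a, collapse = " > ")))
  cat(sprintf("  %s ordering: %s\n", x$scope_b, paste(x$order_b, collapse = " > ")))
  cat(sprintf("  top-k overlap: %s\n", paste(x$top_k_overlap, collapse = ", ")))
  invisible(x)
}

#' Plain-text cluster report
#'
#' Formats a results-table-style report: statements grouped under cluster
#' headers with their mean ratings, cluster aggregates bolded by convention
#' as `mean (sd)` on the header line.
#'
#' @param solution `cm_solution`.
#' @param statements `cm_statements`.
#' @param summary `cm_cluster_summary` built from the same solution.
#' @param labels optional output of [suggest_labels()]; top candidate is
#'   shown as the cluster title.
#' @return character vector of report lines.
#' @export
format_cluster_report <- function(solution, statements, summary,
                                  labels = NULL) {
  sm <- attr(summary, "statement_means")
  lines <- character()
  for (i in seq_len(nrow(summary))) {
    cl <- summary$cluster[i]
    title <- sprintf("Cluster %d", cl)
    lab <- if (!is.null(labels)) labels[[as.character(cl)]] else NULL
    if (!is.null(lab) && nrow(lab))
      title <- sprintf("Cluster %d: %s", cl, lab$label[1])
    lines <- c(lines, sprintf("%s -- %.2f (%.2f)", title,
                              round_half_up(summary$mean[i], 2),
                              round_half_up(summary$sd[i], 2)))
    ids <- as.integer(names(solution$assignment)[solution$assignment == cl])
    for (id in sort(ids)) {
      txt <- statements$text[statements$statement_id == id]
      lines <- c(lines, sprintf("  %2d  %-60s %.2f", id,
                                substr(txt, 1, 60), round_half_up(sm[as.character(id)], 2)))
    }
    lines <- c(lines, "")
  }
  lines
}
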