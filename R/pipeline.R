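#' Run the full concept-mapping pipeline
#'
#' Executes similarity -> ordination -> clustering -> labeling -> rating
#' summaries -> pattern match on a dataset, writing every canonical export
#' plus a JSON run manifest into `output_dir`. In `"ratings_only"` mode the
#' sort-based stages are skipped and a supplied cluster `membership` is
#' summarized instead (useful to recompute a published results table from
#' its printed statement ratings).
#'
#' @param x a `cm_dataset` or a directory readable by [read_dataset()].
#' @param output_dir directory for exports (created if needed).
#' @param seed integer seed for the MDS starts.
#' @param k number of clusters to cut for the reported solution.
#' @param k_range optional `c(k_min, k_max)`; all cuts are exported.
#' @param n_starts,max_iter,tol MDS settings.
#' @param scopes rating scopes to summarize.
#' @param mode `"full"` or `"ratings_only"`.
#' @param membership cluster membership (data frame `statement_id,cluster`)
#'   required in `"ratings_only"` mode.
#' @param means optional precomputed statement means (data frame
#'   `statement_id,mean`) used as the `"all"` scope when the dataset carries
#'   no per-rater ratings (e.g. recomputing a published results table).
#' @param figures write SVG figures (requires cairo support).
#' @param verbose log stage progress via `message()`.
#' @return the manifest list, invisibly.
#' @export
run_pipeline <- function(x, output_dir, seed = 1L, k = 7L, k_range = NULL,
                         n_starts = 10L, max_iter = 500L, tol = 1e-6,
                         scopes = c("all", "consumer", "provider"),
                         mode = c("full", "ratings_only"), membership = NULL,
                         means = NULL, figures = FALSE, verbose = TRUE) {
  mode <- match.arg(mode)
  dataset <- if (inherits(x, "cm_dataset")) x else read_dataset(x)
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  log <- function(...) if (verbose) message(sprintf(...))
  files <- character()
  add_file <- function(f) files <<- c(files, basename(f))

  pm <- NULL; tree <- NULL; labels <- NULL
  if (mode == "full") {
    if (!length(dataset$sorts))
      cm_abort("stage 'similarity': no sort records in the dataset")
    log("stage similarity: %d sorters, %d statements",
        length(dataset$sorts), nrow(dataset$statements))
    sim <- aggregate_similarity(dataset$sorts, dataset$statements)
    f <- file.path(output_dir, "similarity.tsv")
    write_matrix_tsv(sim, f); add_file(f)
    jsonlite::write_json(list(n_sorters = attr(sim, "n_sorters"),
                              transform = "count_complement"),
                         file.path(output_dir, "similarity_meta.json"),
                         auto_unbox = TRUE)
    add_file(file.path(output_dir, "similarity_meta.json"))
    dis <- to_dissimilarity(sim)
    log("stage ordination: nonmetric MDS, %d starts", n_starts)
    pm <- nonmetric_mds(dis, seed = seed, n_starts = n_starts,
                        max_iter = max_iter, tol = tol)
    log("  stress-1 = %.4f", pm$stress)
    f <- file.path(output_dir, "point_map.csv")
    write.csv(data.frame(statement_id = rownames(pm$coordinates),
                         x = pm$coordinates[, 1], y = pm$coordinates[, 2]),
              f, row.names = FALSE); add_file(f)
    jsonlite::write_json(c(pm$config, list(stress = pm$stress,
                                           converged = pm$converged,
                                           n_iter = pm$n_iter)),
                         file.path(output_dir, "point_map_meta.json"),
                         auto_unbox = TRUE)
    add_file(file.path(output_dir, "point_map_meta.json"))
    log("stage clustering: ward tree, cut at k = %d", k)
    tree <- ward_tree(pm)
    jsonlite::write_json(merge_table(tree),
                         file.path(output_dir, "merge_tree.json"))
    add_file(file.path(output_dir, "merge_tree.json"))
    solution <- cut_tree(tree, k)
    if (!is.null(k_range)) {
      sols <- solution_range(tree, k_range[1], k_range[2])
      for (nm in names(sols)) {
        f <- file.path(output_dir, sprintf("solution_%s.csv", nm))
        write_solution_csv(sols[[nm]], f); add_file(f)
      }
    }
    log("stage labeling")
    labels <- suggest_labels(solution, dataset$sorts)
    lab_df <- do.call(rbind, lapply(names(labels), function(cl) {
      d <- head(labels[[cl]], 5)
      if (!nrow(d)) return(NULL)
      cbind(cluster = as.integer(cl), d)
    }))
    f <- file.path(output_dir, "labels.csv")
    write.csv(lab_df %||% data.frame(), f, row.names = FALSE); add_file(f)
  } else {
    if (is.null(membership))
      cm_abort("ratings_only mode needs a membership table")
    solution <- as_solution(membership)
  }
  f <- file.path(output_dir, "solution.csv")
  write_solution_csv(solution, f); add_file(f)

  log("stage ratings: scopes %s", paste(scopes, collapse = ", "))
  summaries <- list()
  for (sc in scopes) {
    sm <- if (sc == "all" && !is.null(means)) means
          else withCallingHandlers(statement_means(dataset$ratings, sc),
                                   warning = function(w) invokeRestart("muffleWarning"))
    if (!nrow(sm)) next
    if (!all(names(solution$assignment) %in% as.character(sm$statement_id))) next
    cs <- cluster_summary(solution, sm, scope = sc)
    summaries[[sc]] <- cs
    f <- file.path(output_dir, sprintf("summary_%s.csv", sc))
    out <- as.data.frame(cs)
    out$scope <- sc
    write.csv(out[c("cluster", "scope", "n_statements", "mean", "sd")], f,
              row.names = FALSE)
    add_file(f)
  }
  if (!is.null(summaries$all)) {
    rep_lines <- format_cluster_report(solution, dataset$statements,
                                       summaries$all, labels)
    f <- file.path(output_dir, "cluster_report.txt")
    writeLines(rep_lines, f); add_file(f)
  }
  pmatch <- NULL
  if (!is.null(summaries$consumer) && !is.null(summaries$provider)) {
    log("stage pattern match: consumer vs provider")
    pmatch <- pattern_match(summaries$consumer, summaries$provider)
    f <- file.path(output_dir, "pattern_match.csv")
    write.csv(data.frame(cluster = pmatch$clusters,
                         consumer_mean = pmatch$mean_a,
                         provider_mean = pmatch$mean_b), f, row.names = FALSE)
    add_file(f)
    jsonlite::write_json(list(correlation = pmatch$correlation,
                              method = pmatch$method,
                              order_consumer = pmatch$order_a,
                              order_provider = pmatch$order_b,
                              top_k_overlap = pmatch$top_k_overlap),
                         file.path(output_dir, "pattern_match.json"),
                         auto_unbox = TRUE)
    add_file(file.path(output_dir, "pattern_match.json"))
  }
  if (figures && mode == "full") {
    log("stage figures")
    figs <- render_maps(pm, solution, pmatch, output_dir)
    files <- c(files, basename(figs))
  }
  manifest <- list(
    package_version = as.character(utils::packageVersion("conceptmapr")),
    mode = mode, seed = as.integer(seed), k = solution$k,
    mds = if (!is.null(pm)) pm$config else NULL,
    stress = if (!is.null(pm)) pm$stress else NULL,
    cluster_sizes = as.integer(table(solution$assignment)),
    scopes = names(summaries),
    pattern_match_correlation = if (!is.null(pmatch)) pmatch$correlation else NULL,
    files = unique(files))
  jsonlite::write_json(manifest, file.path(output_dir, "run_manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

write_matrix_tsv <- function(m, path) {
  df <- as.data.frame(unclass(m))
  names(df) <- rownames(m)
  df <- cbind(statement_id = rownames(m), df)
  write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
}

#' Read a similarity matrix exported by the pipeline
#'
#' @param path TSV written by the pipeline (header row + ID column).
#' @param meta optional path to the JSON sidecar carrying `n_sorters`.
#' @return `cm_similarity`.
#' @export
read_similarity_tsv <- function(path, meta = NULL) {
  df <- read.csv(path, sep = "\t", check.names = FALSE)
  ids <- df$statement_id
  m <- as.matrix(df[, -1, drop = FALSE])
  dimnames(m) <- list(ids, ids)
  n <- if (!is.null(meta)) jsonlite::read_json(meta)$n_sorters else max(diag(m))
  structure(m, n_sorters = n, statement_ids = as.integer(ids),
            class = c("cm_similarity", "matrix", "array"))
}

write_solution_csv <- function(solution, path) {
  write.csv(data.frame(statement_id = names(solution$assignment),
                       cluster = solution$assignment),
            path, row.names = FALSE)
}
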