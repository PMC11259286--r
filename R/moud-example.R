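#' Packaged example: barriers to medication for opioid use disorder
#'
#' A 70-statement community concept-mapping exercise on what makes
#' medication for opioid use disorder (MOUD, e.g. buprenorphine) difficult
#' to start or keep using. The package ships the statement list, the
#' importance means pooled over 57 raters (23 consumers with lived
#' experience of OUD and 34 service providers), and the published
#' seven-cluster thematic grouping of the statements. The raw sort and
#' per-rater rating records of that exercise are not public, so the example
#' supports the ratings-side analyses (cluster summaries, reports) and
#' serves as a realistic statement set for simulation; sort-side stages are
#' exercised on synthetic data from [generate_dataset()].
#'
#' @return list with `statements` (`cm_statements`), `statement_means`
#'   (data frame `statement_id, mean, n_raters`), `membership` (data frame
#'   `statement_id, cluster, cluster_label`) and `cluster_labels`
#'   (character vector indexed by cluster).
#' @export
#' @examples
#' ex <- moud_example()
#' sol <- as_solution(ex$membership)
#' cluster_summary(sol, ex$statement_means)
moud_example <- function() {
  path <- function(f) system.file("extdata", f, package = "conceptmapr",
                                  mustWork = TRUE)
  statements <- read_statements(path("moud_statements.csv"))
  ratings <- read.csv(path("moud_statement_ratings.csv"))
  means <- data.frame(statement_id = as.integer(ratings$statement_id),
                      mean = as.numeric(ratings$mean_rating),
                      n_raters = as.integer(ratings$n_raters))
  membership <- read.csv(path("moud_cluster_membership.csv"),
                         stringsAsFactors = FALSE)
  labels <- tapply(membership$cluster_label, membership$cluster,
                   function(x) x[1])
  list(statements = statements,
       statement_means = means,
       membership = membership,
       cluster_labels = as.character(labels))
}
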