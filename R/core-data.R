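#' Statements, sort records and rating records
#'
#' A concept-mapping study revolves around three tables: the brainstormed
#' statement set, each sorter's partition of the statements into labeled
#' piles, and each rater's 1-5 importance ratings. These constructors
#' validate the invariants that the downstream multivariate analysis relies
#' on (unique statement IDs, exact-partition sorts, integer in-range
#' ratings).
#'
#' @param statements data frame with columns `statement_id` (positive
#'   integers, unique) and `text` (non-empty after trimming).
#' @return `cm_statements`, a validated data frame.
#' @export
#' @examples
#' new_statements(data.frame(statement_id = 1:3, text = c("a", "b", "c")))
new_statements <- function(statements) {
  if (!is.data.frame(statements) ||
      !all(c("statement_id", "text") %in% names(statements)))
    cm_abort("statements must be a data frame with columns statement_id, text")
  ids <- statements$statement_id
  if (any(is.na(ids)) || any(ids != as.integer(ids)) || any(ids < 1))
    cm_abort("statement_id must be positive integers")
  dup <- unique(ids[duplicated(ids)])
  if (length(dup))
    cm_abort(sprintf("duplicate statement_id: %s", paste(dup, collapse = ", ")))
  txt <- trimws(as.character(statements$text))
  bad <- ids[!nzchar(txt)]
  if (length(bad))
    cm_abort(sprintf("empty statement text for id: %s", paste(bad, collapse = ", ")))
  out <- data.frame(statement_id = as.integer(ids), text = txt,
                    stringsAsFactors = FALSE)
  class(out) <- c("cm_statements", "data.frame")
  out
}

#' @export
print.cm_statements <- function(x, ...) {
  cat(sprintf("Statement set: %d statements (ids %d..%d)\n",
              nrow(x), min(x$statement_id), max(x$statement_id)))
  print.data.frame(head(as.data.frame(x), 6))
  if (nrow(x) > 6) cat(sprintf("... %d more\n", nrow(x) - 6L))
  invisible(x)
}

#' Construct one sorter's pile partition
#'
#' @param sorter_id character scalar.
#' @param piles list of piles, each a list with elements `label` (character,
#'   may be `""`: pile titles are participant free text) and `members`
#'   (integer statement IDs). Piles must be non-empty and pairwise disjoint.
#' @param statements optional `cm_statements`; when supplied the piles must
#'   partition it exactly.
#' @return a `cm_sort` record.
#' @export
new_sort <- function(sorter_id, piles, statements = NULL) {
  if (!length(piles)) cm_abort(sprintf("sorter %s: no piles", sorter_id))
  piles <- unname(lapply(piles, function(p) {
    if (!length(p$members)) cm_abort(sprintf("sorter %s: empty pile", sorter_id))
    list(label = as.character(p$label %||% ""),
         members = sort(as.integer(p$members)))
  }))
  all_members <- unlist(lapply(piles, `[[`, "members"))
  dup <- unique(all_members[duplicated(all_members)])
  if (length(dup))
    cm_abort(sprintf("sorter %s: statement %s appears in more than one pile",
                     sorter_id, paste(dup, collapse = ", ")))
  rec <- structure(list(sorter_id = as.character(sorter_id), piles = piles),
                   class = "cm_sort")
  if (!is.null(statements)) validate_sort(rec, statements)
  rec
}

validate_sort <- function(sort, statements) {
  ids <- statements$statement_id
  members <- unlist(lapply(sort$piles, `[[`, "members"))
  unknown <- setdiff(members, ids)
  if (length(unknown))
    cm_abort(sprintf("sorter %s references unknown statement_id: %s",
                     sort$sorter_id, paste(unknown, collapse = ", ")))
  missing <- setdiff(ids, members)
  if (length(missing))
    cm_abort(sprintf("sorter %s: incomplete sort, missing statement_id: %s",
                     sort$sorter_id, paste(missing, collapse = ", ")),
             class = "cm_incomplete_sort_error")
  invisible(sort)
}

#' @export
print.cm_sort <- function(x, ...) {
  cat(sprintf("Sort %s: %d piles (%s)\n", x$sorter_id, length(x$piles),
              paste(vapply(x$piles, function(p) length(p$members), 1L),
                    collapse = "+")))
  invisible(x)
}

#' Read a statement list from CSV
#'
#' Expects header `statement_id,text` (RFC-4180 quoting). File order is
#' preserved.
#'
#' @param path path to a statements CSV.
#' @return `cm_statements`.
#' @export
read_statements <- function(path) {
  if (!file.exists(path)) cm_abort(sprintf("file not found: %s", path))
  df <- read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  new_statements(df)
}

#' Read sort records from long-format CSV
#'
#' Expects header `sorter_id,pile_label,statement_id`, one row per card
#' placement. Rows sharing a `(sorter_id, pile_label)` pair form one pile;
#' pile order is order of first appearance.
#'
#' @param path path to a sorts CSV.
#' @param statements `cm_statements` the sorts must partition.
#' @param incomplete `"error"` (default: a sorter not covering every
#'   statement is a hard error) or `"drop"` (drop that sorter with a
#'   warning). In-person card sorting normally yields complete sorts, so
#'   strict is the default.
#' @return `cm_sorts`: a list of `cm_sort` records, one per sorter, in
#'   sorter order of first appearance.
#' @export
read_sorts <- function(path, statements, incomplete = c("error", "drop")) {
  incomplete <- match.arg(incomplete)
  if (!file.exists(path)) cm_abort(sprintf("file not found: %s", path))
  df <- read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8",
                 colClasses = c(sorter_id = "character",
                                pile_label = "character"))
  if (!all(c("sorter_id", "pile_label", "statement_id") %in% names(df)))
    cm_abort("sorts CSV needs columns sorter_id, pile_label, statement_id")
  df$pile_label[is.na(df$pile_label)] <- ""
  out <- list()
  dropped <- character()
  for (sid in unique(df$sorter_id)) {
    rows <- df[df$sorter_id == sid, , drop = FALSE]
    labs <- unique(rows$pile_label)
    piles <- lapply(labs, function(l)
      list(label = l, members = rows$statement_id[rows$pile_label == l]))
    rec <- tryCatch(new_sort(sid, piles, statements), cm_incomplete_sort_error =
      function(e) {
        if (incomplete == "error") stop(e)
        dropped <<- c(dropped, sid)
        NULL
      })
    if (!is.null(rec)) out[[length(out) + 1L]] <- rec
  }
  if (length(dropped))
    warning(sprintf("dropped %d incomplete sorter(s): %s",
                    length(dropped), paste(dropped, collapse = ", ")))
  structure(out, class = "cm_sorts")
}

#' Read rating records from long-format CSV
#'
#' Expects header `rater_id,group,statement_id,rating` with
#' `group` one of `consumer`, `provider`, `other` and integer ratings on the
#' 1-5 importance scale. Ratings may be partial (a rater need not rate every
#' statement); statement means later use available raters only.
#'
#' @param path path to a ratings CSV.
#' @param statements `cm_statements` the ratings must reference.
#' @return `cm_ratings`: a long data frame (rater_id, group, statement_id,
#'   rating), validated.
#' @export
read_ratings <- function(path, statements) {
  if (!file.exists(path)) cm_abort(sprintf("file not found: %s", path))
  df <- read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8",
                 colClasses = c(rater_id = "character", group = "character"))
  new_ratings(df, statements)
}

#' @rdname read_ratings
#' @param ratings long data frame to validate in place of a file.
#' @export
new_ratings <- function(ratings, statements = NULL) {
  need <- c("rater_id", "group", "statement_id", "rating")
  if (!is.data.frame(ratings) || !all(need %in% names(ratings)))
    cm_abort("ratings need columns rater_id, group, statement_id, rating")
  df <- as.data.frame(ratings)[need]
  bad_group <- setdiff(unique(df$group), c("consumer", "provider", "other"))
  if (length(bad_group))
    cm_abort(sprintf("unknown rater group: %s", paste(bad_group, collapse = ", ")))
  r <- df$rating
  if (any(is.na(r)) || any(r != as.integer(r)) || any(r < 1) || any(r > 5))
    cm_abort("ratings must be integers in [1, 5]")
  key <- paste(df$rater_id, df$statement_id)
  if (anyDuplicated(key)) {
    d <- key[duplicated(key)][1]
    cm_abort(sprintf("duplicate rating for (rater, statement) = (%s)", d))
  }
  grp_per_rater <- tapply(df$group, df$rater_id, function(g) length(unique(g)))
  if (any(grp_per_rater > 1))
    cm_abort("a rater_id appears with more than one group tag")
  if (!is.null(statements)) {
    unknown <- setdiff(df$statement_id, statements$statement_id)
    if (length(unknown))
      cm_abort(sprintf("ratings reference unknown statement_id: %s",
                       paste(unknown, collapse = ", ")))
  }
  df$statement_id <- as.integer(df$statement_id)
  df$rating <- as.integer(df$rating)
  rownames(df) <- NULL
  class(df) <- c("cm_ratings", "data.frame")
  df
}

#' Bundle statements, sorts and ratings into one dataset
#'
#' @param statements `cm_statements`.
#' @param sorts `cm_sorts` (may be empty list).
#' @param ratings `cm_ratings` (may be empty data frame).
#' @param metadata free-form list.
#' @return `cm_dataset`.
#' @export
new_dataset <- function(statements, sorts = list(), ratings = NULL,
                        metadata = list()) {
  statements <- if (inherits(statements, "cm_statements")) statements else
    new_statements(statements)
  for (s in sorts) validate_sort(s, statements)
  if (is.null(ratings))
    ratings <- new_ratings(data.frame(rater_id = character(),
                                      group = character(),
                                      statement_id = integer(),
                                      rating = integer()))
  else if (!inherits(ratings, "cm_ratings"))
    ratings <- new_ratings(ratings, statements)
  else new_ratings(as.data.frame(ratings), statements)
  structure(list(statements = statements,
                 sorts = structure(sorts, class = "cm_sorts"),
                 ratings = ratings, metadata = metadata),
            class = "cm_dataset")
}

#' @export
print.cm_dataset <- function(x, ...) {
  grp <- table(x$ratings$group[!duplicated(x$ratings$rater_id)])
  cat(sprintf("Concept-mapping dataset: %d statements, %d sorters, %d raters (%s)\n",
              nrow(x$statements), length(x$sorts),
              length(unique(x$ratings$rater_id)),
              paste(sprintf("%s=%d", names(grp), grp), collapse = ", ")))
  invisible(x)
}

sorts_to_long <- function(sorts) {
  rows <- lapply(sorts, function(s) {
    do.call(rbind, lapply(s$piles, function(p)
      data.frame(sorter_id = s$sorter_id, pile_label = p$label,
                 statement_id = p$members, stringsAsFactors = FALSE)))
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(sorter_id = character(), pile_label = character(),
                      statement_id = integer())
  rownames(out) <- NULL
  out
}

#' Write a dataset to its canonical CSV files
#'
#' Writes `statements.csv`, `sorts.csv`, `ratings.csv` and a JSON
#' `manifest.json` (row counts, statement count, sorter count, rater counts
#' per group) into `directory`. `read_dataset()` on that directory
#' reproduces an equal dataset.
#'
#' @param dataset `cm_dataset`.
#' @param directory output directory (created if needed).
#' @return the manifest list, invisibly.
#' @export
write_dataset <- function(dataset, directory) {
  dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  paths <- file.path(directory, c("statements.csv", "sorts.csv", "ratings.csv"))
  write.csv(as.data.frame(dataset$statements), paths[1], row.names = FALSE)
  long <- sorts_to_long(dataset$sorts)
  write.csv(long, paths[2], row.names = FALSE)
  write.csv(as.data.frame(dataset$ratings), paths[3], row.names = FALSE)
  grp <- table(dataset$ratings$group[!duplicated(dataset$ratings$rater_id)])
  manifest <- list(
    files = basename(paths),
    n_statements = nrow(dataset$statements),
    n_sorters = length(dataset$sorts),
    n_raters = as.list(structure(as.integer(grp), names = names(grp))),
    rows = list(statements = nrow(dataset$statements), sorts = nrow(long),
                ratings = nrow(dataset$ratings)))
  jsonlite::write_json(manifest, file.path(directory, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(directory) {
  statements <- read_statements(file.path(directory, "statements.csv"))
  sorts_path <- file.path(directory, "sorts.csv")
  ratings_path <- file.path(directory, "ratings.csv")
  sorts <- if (file.exists(sorts_path) &&
               nrow(read.csv(sorts_path)) > 0)
    read_sorts(sorts_path, statements) else structure(list(), class = "cm_sorts")
  ratings <- if (file.exists(ratings_path)) read_ratings(ratings_path, statements)
             else NULL
  new_dataset(statements, sorts, ratings)
}

#' Flag degenerate sorters
#'
#' "Lumpers" who put every statement in one pile and "splitters" who make
#' every statement a singleton contribute no (or trivial) co-occurrence
#' information. Practice varies on whether to exclude them; the pipeline
#' retains them by default and this report makes them visible.
#'
#' @param sorts `cm_sorts`.
#' @param statements `cm_statements`.
#' @return data frame (sorter_id, n_piles, all_in_one_pile, all_singletons).
#' @export
sort_quality <- function(sorts, statements) {
  S <- nrow(statements)
  do.call(rbind, lapply(sorts, function(s) data.frame(
    sorter_id = s$sorter_id,
    n_piles = length(s$piles),
    all_in_one_pile = length(s$piles) == 1L,
    all_singletons = length(s$piles) == S,
    stringsAsFactors = FALSE)))
}
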