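#' Configuration for the synthetic sort-and-rate generator
#'
#' The defaults emulate the scale of a typical community concept-mapping
#' study: 70 statements, a planted 7-cluster thematic structure, 23 sorters
#' (consumers, who also rate), and a second rate-only group of 34 providers.
#' Sorter noise is three-layered to mimic documented "lumper/splitter"
#' behavior: with probability `split_prob` a sorter splits one planted
#' cluster in two, with probability `merge_prob` they merge two clusters,
#' and then every statement independently jumps to a different pile with
#' probability `epsilon`.
#'
#' Ratings are generated from a latent value per (group, statement):
#' group baseline + group-specific cluster effect + statement effect (drawn
#' once per statement, SD `statement_effect_sd`) + per-rater noise (SD
#' `rating_noise_sd`), discretized by round-then-clip to the 1-5 Likert
#' scale. Default cluster effects decline across clusters for both groups,
#' with the two groups' orderings permuted (top ranks swapped) so the
#' planted pattern match shares top clusters in a different order.
#'
#' @param S statement count.
#' @param K planted cluster count.
#' @param cluster_sizes optional integer vector summing to `S` (default:
#'   as equal as possible).
#' @param n_sorters number of sorters.
#' @param epsilon per-statement misplacement probability.
#' @param merge_prob,split_prob per-sorter structural-noise probabilities.
#' @param group_sizes named integer vector of rater counts per group.
#' @param group_baselines named numeric vector, latent baseline per group.
#' @param group_cluster_effects optional numeric matrix (groups x K) of
#'   latent cluster offsets; `NULL` builds the default described above.
#' @param statement_effect_sd,rating_noise_sd latent noise SDs.
#' @param seed integer; one global seed drives a named sub-stream per
#'   generator stage, so adding raters does not perturb the sorts.
#' @return `cm_config` list.
#' @export
synthetic_config <- function(S = 70L, K = 7L, cluster_sizes = NULL,
                             n_sorters = 23L,
                             epsilon = 0.15, merge_prob = 0.3,
                             split_prob = 0.3,
                             group_sizes = c(consumer = 23L, provider = 34L),
                             group_baselines = c(consumer = 4.0,
                                                 provider = 3.6,
                                                 other = 3.5),
                             group_cluster_effects = NULL,
                             statement_effect_sd = 0.25,
                             rating_noise_sd = 0.9,
                             seed = 1L) {
  if (!is_count(S, 3L) || !is_count(K, 1L) || K > S)
    cm_abort("need integer S >= 3 and 1 <= K <= S")
  if (!is_count(n_sorters, 1L)) cm_abort("n_sorters must be a positive integer")
  if (!all(vapply(c(epsilon, merge_prob, split_prob), is_prob, logical(1))))
    cm_abort("epsilon, merge_prob, split_prob must be probabilities in [0, 1]")
  if (is.null(cluster_sizes)) {
    base <- S %/% K
    cluster_sizes <- rep(base, K) + as.integer(seq_len(K) <= S %% K)
  }
  if (length(cluster_sizes) != K || sum(cluster_sizes) != S ||
      any(cluster_sizes < 1))
    cm_abort("cluster_sizes must be K positive integers summing to S")
  groups <- names(group_sizes)
  if (is.null(groups) || !all(groups %in% c("consumer", "provider", "other")))
    cm_abort("group_sizes must be named with consumer/provider/other")
  if (is.null(group_cluster_effects)) {
    eff <- seq(0.35, -0.35, length.out = K)
    m <- matrix(rep(eff, each = length(groups)), nrow = length(groups),
                dimnames = list(groups, NULL))
    if (K >= 3 && length(groups) >= 2) {
      # second group: swap ranks 1<->2 and the two least important clusters
      m[2, c(1, 2)] <- m[2, c(2, 1)]
      if (K >= 5) m[2, c(K - 1, K)] <- m[2, c(K, K - 1)]
    }
    group_cluster_effects <- m
  }
  if (!is.matrix(group_cluster_effects) ||
      ncol(group_cluster_effects) != K ||
      !all(groups %in% rownames(group_cluster_effects)))
    cm_abort("group_cluster_effects must be a groups x K matrix")
  if (statement_effect_sd < 0 || rating_noise_sd < 0)
    cm_abort("noise SDs must be non-negative")
  structure(list(S = as.integer(S), K = as.integer(K),
                 cluster_sizes = as.integer(cluster_sizes),
                 n_sorters = as.integer(n_sorters),
                 epsilon = epsilon, merge_prob = merge_prob,
                 split_prob = split_prob,
                 group_sizes = group_sizes,
                 group_baselines = group_baselines,
                 group_cluster_effects = group_cluster_effects,
                 statement_effect_sd = statement_effect_sd,
                 rating_noise_sd = rating_noise_sd,
                 seed = as.integer(seed)),
            class = "cm_config")
}

planted_partition <- function(config) {
  structure(rep(seq_len(config$K), config$cluster_sizes),
            names = seq_len(config$S))
}

#' Generate card sorts with planted cluster structure
#'
#' Every sorter starts from the planted partition, optionally splits one
#' cluster and/or merges two (structural noise), then each statement moves
#' to a uniformly chosen different pile with probability `epsilon`. Pile
#' labels are cluster-tagged strings (`"theme-03 ..."`) so label recovery
#' is testable. Fully reproducible from `config$seed`.
#'
#' @param config `cm_config`.
#' @return list with `sorts` (`cm_sorts`) and `ground_truth`
#'   (`planted_partition`: statement ID -> planted cluster).
#' @export
generate_sorts <- function(config) {
  stopifnot(inherits(config, "cm_config"))
  seeds <- stage_seeds(config$seed, 2L)
  set.seed(seeds[1])
  partition <- planted_partition(config)
  sorts <- vector("list", config$n_sorters)
  for (i in seq_len(config$n_sorters)) {
    piles <- split(as.integer(names(partition)), partition)
    tags <- as.integer(names(piles))
    # structural noise: split one cluster, merge two clusters
    if (runif(1) < config$split_prob) {
      big <- which(lengths(piles) >= 2)
      if (length(big)) {
        j <- big[sample.int(length(big), 1)]
        memb <- piles[[j]]
        m <- sample.int(length(memb) - 1L, 1)
        left <- sort(sample(memb, m))
        piles[[j]] <- left
        piles <- c(piles, list(setdiff(memb, left)))
        tags <- c(tags, tags[j])
      }
    }
    if (runif(1) < config$merge_prob && length(piles) >= 2) {
      pair <- sample.int(length(piles), 2)
      piles[[pair[1]]] <- sort(c(piles[[pair[1]]], piles[[pair[2]]]))
      tags[pair[1]] <- min(tags[pair])
      piles <- piles[-pair[2]]
      tags <- tags[-pair[2]]
    }
    # per-statement jitter
    if (config$epsilon > 0 && length(piles) >= 2) {
      for (s in seq_len(config$S)) {
        if (runif(1) < config$epsilon) {
          from <- which(vapply(piles, function(p) s %in% p, logical(1)))
          cand <- setdiff(seq_along(piles), from)
          to <- cand[sample.int(length(cand), 1)]
          piles[[from]] <- setdiff(piles[[from]], s)
          piles[[to]] <- sort(c(piles[[to]], s))
          if (!length(piles[[from]])) {
            piles <- piles[-from]
            tags <- tags[-from]
          }
        }
      }
    }
    sorts[[i]] <- new_sort(
      sprintf("S%02d", i),
      Map(function(memb, tag, j)
        list(label = sprintf("theme-%02d (s%02d.%d)", tag, i, j),
             members = memb),
        piles, tags, seq_along(piles)))
  }
  list(sorts = structure(sorts, class = "cm_sorts"),
       ground_truth = list(planted_partition = partition))
}

#' Generate Likert ratings with planted cluster effects
#'
#' @param config `cm_config`.
#' @param ground_truth output of [generate_sorts()] (`$ground_truth`), for
#'   the planted partition.
#' @return list with `ratings` (`cm_ratings`) and `ground_truth` augmented
#'   with `planted_statement_means` (groups x S latent means before
#'   discretization).
#' @export
generate_ratings <- function(config, ground_truth) {
  stopifnot(inherits(config, "cm_config"))
  seeds <- stage_seeds(config$seed, 2L)
  set.seed(seeds[2])
  partition <- ground_truth$planted_partition
  S <- config$S
  stmt_eff <- rnorm(S, 0, config$statement_effect_sd)
  groups <- names(config$group_sizes)
  latent <- matrix(NA_real_, length(groups), S,
                   dimnames = list(groups, names(partition)))
  for (g in groups)
    latent[g, ] <- config$group_baselines[[g]] +
      config$group_cluster_effects[g, partition] + stmt_eff
  rows <- list()
  prefix <- c(consumer = "C", provider = "P", other = "O")
  for (g in groups) {
    ng <- config$group_sizes[[g]]
    for (r in seq_len(ng)) {
      vals <- latent[g, ] + rnorm(S, 0, config$rating_noise_sd)
      vals <- pmin(5, pmax(1, round_half_up(vals, 0)))
      rows[[length(rows) + 1L]] <- data.frame(
        rater_id = sprintf("%s%02d", prefix[[g]], r), group = g,
        statement_id = seq_len(S), rating = as.integer(vals),
        stringsAsFactors = FALSE)
    }
  }
  ratings <- new_ratings(do.call(rbind, rows))
  ground_truth$planted_statement_means <- latent
  list(ratings = ratings, ground_truth = ground_truth)
}

#' Generate a complete synthetic concept-mapping dataset
#'
#' @param config `cm_config`.
#' @return list with `dataset` (`cm_dataset`, statements carry synthetic
#'   placeholder texts) and `ground_truth`.
#' @export
generate_dataset <- function(config = synthetic_config()) {
  so <- generate_sorts(config)
  ra <- generate_ratings(config, so$ground_truth)
  statements <- new_statements(data.frame(
    statement_id = seq_len(config$S),
    text = sprintf("synthetic statement %02d", seq_len(config$S))))
  dataset <- new_dataset(statements, so$sorts, ra$ratings,
                         metadata = list(synthetic = TRUE,
                                         seed = config$seed))
  list(dataset = dataset, ground_truth = ra$ground_truth, config = config)
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected pair-counting agreement, computed from the contingency
#' table: `(sum_ij C(n_ij,2) - E) / (0.5*(a + b) - E)` with
#' `E = a*b / C(n,2)`, `a = sum_i C(n_i.,2)`, `b = sum_j C(n_.j,2)`.
#'
#' @param a,b cluster assignments of the same elements (vectors, any labels).
#' @return ARI in \[-1, 1\]; 1 for identical partitions, about 0 for
#'   independent ones.
#' @export
adjusted_rand_index <- function(a, b) {
  if (length(a) != length(b)) cm_abort("partitions differ in length")
  comb2 <- function(n) n * (n - 1) / 2
  tab <- table(a, b)
  sum_ij <- sum(comb2(tab))
  sum_i <- sum(comb2(rowSums(tab)))
  sum_j <- sum(comb2(colSums(tab)))
  expected <- sum_i * sum_j / comb2(length(a))
  denom <- (sum_i + sum_j) / 2 - expected
  if (denom == 0) return(1)  # both partitions trivial (all-one-cluster etc.)
  (sum_ij - expected) / denom
}

#' Planted-structure recovery report
#'
#' Runs the full pipeline (similarity -> nonmetric MDS -> Ward clustering
#' at k = K -> label suggestion) on a synthetic dataset and scores recovery
#' against the ground truth: adjusted Rand index of the recovered partition,
#' the fraction of clusters whose top suggested label carries the planted
#' cluster tag of the cluster's majority, and the map stress.
#'
#' @param dataset `cm_dataset` from [generate_dataset()].
#' @param ground_truth matching ground truth.
#' @param k clusters to cut (default: number of planted clusters).
#' @param seed,n_starts,max_iter,tol MDS settings (see [nonmetric_mds()]).
#' @return list `(ari, label_recovery_rate, stress, point_map, solution)`.
#' @export
recovery_report <- function(dataset, ground_truth, k = NULL, seed = 1L,
                            n_starts = 10L, max_iter = 500L, tol = 1e-6) {
  partition <- ground_truth$planted_partition
  if (is.null(k)) k <- length(unique(partition))
  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e)
      cm_abort(sprintf("pipeline failed at stage '%s': %s", stage,
                       conditionMessage(e)), class = "cm_computation_error"))
  }
  sim <- run_stage("similarity",
                   aggregate_similarity(dataset$sorts, dataset$statements))
  dis <- run_stage("dissimilarity", to_dissimilarity(sim))
  pm <- run_stage("ordination",
                  nonmetric_mds(dis, seed = seed, n_starts = n_starts,
                                max_iter = max_iter, tol = tol))
  tree <- run_stage("clustering", ward_tree(pm))
  sol <- run_stage("clustering", cut_tree(tree, k))
  labels <- run_stage("labeling", suggest_labels(sol, dataset$sorts))
  ids <- names(sol$assignment)
  ari <- adjusted_rand_index(sol$assignment, partition[ids])
  hits <- vapply(sort(unique(sol$assignment)), function(cl) {
    members <- ids[sol$assignment == cl]
    tab <- table(partition[members])
    majority <- as.integer(names(tab)[which.max(tab)])
    lab <- labels[[as.character(cl)]]
    if (is.null(lab) || !nrow(lab)) return(NA)
    tag <- as.integer(sub("^theme-(\\d+).*$", "\\1", lab$label[1]))
    isTRUE(tag == majority)
  }, logical(1))
  list(ari = ari,
       label_recovery_rate = mean(hits, na.rm = TRUE),
       stress = pm$stress,
       point_map = pm, solution = sol)
}
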