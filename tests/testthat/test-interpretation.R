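test_that("label suggestions rank piles by Jaccard overlap with clusters", {
  st <- toy_statements(4)
  sol <- as_solution(c(`1` = 1L, `2` = 1L, `3` = 1L, `4` = 2L))
  sorts <- as_sorts(toy_sort("A", list(c(1, 2), c(3, 4)), c("a", "b")))
  lab <- suggest_labels(sol, sorts)
  # cluster {1,2,3}: pile a={1,2} -> 2/3; pile b={3,4} -> 1/4
  expect_equal(lab[["1"]]$label, c("a", "b"))
  expect_equal(lab[["1"]]$score, c(2 / 3, 1 / 4))
  # cluster {4}: pile b={3,4} -> 1/2; pile a -> 0
  expect_equal(lab[["2"]]$label[1], "b")
  expect_equal(lab[["2"]]$score[1], 1 / 2)

  # a sorter whose piles equal the clusters scores 1.0 everywhere
  exact <- as_sorts(toy_sort("E", list(c(1, 2, 3), 4), c("first", "second")))
  lab2 <- suggest_labels(sol, exact)
  expect_equal(lab2[["1"]]$label[1], "first")
  expect_equal(lab2[["1"]]$score[1], 1)
  expect_equal(lab2[["2"]]$label[1], "second")
  expect_equal(lab2[["2"]]$score[1], 1)
})

test_that("label ties break by frequency then lexicographically", {
  st <- toy_statements(4)
  sol <- as_solution(c(`1` = 1L, `2` = 1L, `3` = 2L, `4` = 2L))
  # piles "z" and "m" tie on score for cluster 1; "z" occurs twice overall
  sorts <- as_sorts(toy_sort("A", list(c(1, 2), c(3, 4)), c("z", "z")),
                    toy_sort("B", list(c(1, 2), c(3, 4)), c("m", "q")))
  lab <- suggest_labels(sol, sorts)
  expect_equal(lab[["1"]]$label[1], "z")   # frequency 2 beats 1
  # pure lexicographic tie-break: all labels unique, equal scores
  sorts2 <- as_sorts(toy_sort("A", list(c(1, 2), c(3, 4)), c("beta", "x")),
                     toy_sort("B", list(c(1, 2), c(3, 4)), c("alpha", "y")))
  lab2 <- suggest_labels(sol, sorts2)
  expect_equal(lab2[["1"]]$label[1:2], c("alpha", "beta"))

  unlabeled <- as_sorts(toy_sort("A", list(c(1, 2), c(3, 4)), c("", "  ")))
  expect_warning(empty <- suggest_labels(sol, unlabeled), "no labeled piles")
  expect_equal(nrow(empty[["1"]]), 0)
})

test_that("statement means pool available raters in scope", {
  st <- toy_statements(3)
  ratings <- new_ratings(data.frame(
    rater_id = c("R1", "R1", "R2", "R2", "R3", "R3", "R3"),
    group = c("consumer", "consumer", "consumer", "consumer",
              "provider", "provider", "provider"),
    statement_id = c(1, 2, 1, 3, 1, 2, 3),
    rating = c(3, 4, 4, 2, 5, 5, 1)), st)
  all_means <- statement_means(ratings)
  expect_equal(all_means$mean[all_means$statement_id == 1], 4)  # (3+4+5)/3
  # pairwise deletion: statement 2 skipped by R2 -> mean over R1, R3 only
  expect_equal(all_means$mean[all_means$statement_id == 2], 4.5)
  expect_equal(all_means$n_raters[all_means$statement_id == 2], 2L)
  cons <- statement_means(ratings, "consumer")
  expect_equal(cons$mean[cons$statement_id == 1], 3.5)
  expect_warning(none <- statement_means(ratings, "other"), "no ratings")
  expect_equal(nrow(none), 0)
})

test_that("cluster summaries compute mean and population SD of statement means", {
  sol <- as_solution(c(`1` = 1L, `2` = 1L, `3` = 1L, `4` = 2L))
  means <- c(`1` = 3, `2` = 4, `3` = 5, `4` = 2.5)
  cs <- cluster_summary(sol, means)
  expect_equal(cs$mean, c(4, 2.5))
  expect_equal(cs$sd, c(sqrt(2 / 3), 0))    # divide by n, not n - 1
  expect_equal(cs$n_statements, c(3L, 1L))

  # constant statement means: zero variance
  cs2 <- cluster_summary(sol, c(`1` = 3, `2` = 3, `3` = 3, `4` = 3))
  expect_equal(cs2$mean, c(3, 3))
  expect_equal(cs2$sd, c(0, 0))

  expect_error(cluster_summary(sol, means[1:3]), "no rating mean.*4")
  expect_error(cluster_summary(sol, c(means[1:3], `4` = 7)), "\\[1, 5\\]")
})

test_that("cluster means are invariant to rater duplication and bounded", {
  g <- generate_dataset(synthetic_config(S = 12, K = 3, n_sorters = 3,
                                         group_sizes = c(consumer = 5,
                                                         provider = 4),
                                         seed = 17))
  ratings <- g$dataset$ratings
  sol <- as_solution(g$ground_truth$planted_partition)
  cs1 <- cluster_summary(sol, statement_means(ratings))
  doubled <- as.data.frame(ratings)
  doubled2 <- doubled
  doubled2$rater_id <- paste0(doubled2$rater_id, "bis")
  cs2 <- cluster_summary(sol, statement_means(new_ratings(rbind(doubled, doubled2))))
  expect_equal(cs2$mean, cs1$mean)
  expect_equal(cs2$sd, cs1$sd)
  # bounds: min statement mean <= cluster mean <= max statement mean
  sm <- attr(cs1, "statement_means")
  for (i in seq_len(nrow(cs1))) {
    inside <- sm[names(sol$assignment)[sol$assignment == cs1$cluster[i]]]
    expect_gte(cs1$mean[i], min(inside))
    expect_lte(cs1$mean[i], max(inside))
  }
})

test_that("pattern match self-comparison and reversal behave exactly", {
  sol <- as_solution(c(`1` = 1L, `2` = 2L, `3` = 3L))
  a <- cluster_summary(sol, c(`1` = 4, `2` = 3, `3` = 2), scope = "consumer")
  b <- cluster_summary(sol, c(`1` = 2, `2` = 3, `3` = 4), scope = "provider")
  self <- pattern_match(a, a)
  expect_equal(self$correlation, 1)
  expect_equal(self$top_k_overlap, 1:3)
  rev <- pattern_match(a, b)
  expect_equal(rev$correlation, -1)
  expect_equal(rev$top_k_overlap[1], 0L)
  expect_equal(rev$order_a, c(1L, 2L, 3L))
  expect_equal(rev$order_b, c(3L, 2L, 1L))

  sol4 <- as_solution(c(`1` = 1L, `2` = 2L, `3` = 3L, `4` = 4L))
  expect_error(pattern_match(a, cluster_summary(sol4, c(`1` = 1, `2` = 2, `3` = 3, `4` = 4))),
               "different cluster sets")
})

test_that("groups sharing top clusters in different order keep full top-3 overlap", {
  sol <- as_solution(structure(1:5, names = 1:5))
  a <- cluster_summary(sol, c(`1` = 4.5, `2` = 4.3, `3` = 4.1, `4` = 3.0, `5` = 2.8),
                       scope = "consumer")
  b <- cluster_summary(sol, c(`1` = 4.0, `2` = 4.4, `3` = 4.2, `4` = 2.9, `5` = 3.1),
                       scope = "provider")
  pm <- pattern_match(a, b)
  expect_false(identical(pm$order_a[1:3], pm$order_b[1:3]))
  expect_equal(pm$top_k_overlap[3], 3L)
})

test_that("the cluster report lists every statement under its cluster", {
  ex <- moud_example()
  sol <- as_solution(ex$membership)
  cs <- cluster_summary(sol, ex$statement_means)
  lines <- format_cluster_report(sol, ex$statements, cs)
  expect_equal(sum(grepl("^Cluster", lines)), 7)
  expect_equal(sum(grepl("^  ", lines)), 70)
  expect_match(lines[1], "4\\.05")
})
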