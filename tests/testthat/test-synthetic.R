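test_that("generation is deterministic and sorts ignore the rater layout", {
  cfg <- synthetic_config(S = 15, K = 3, n_sorters = 5, seed = 42)
  g1 <- generate_dataset(cfg)
  g2 <- generate_dataset(cfg)
  expect_identical(g1$dataset$sorts, g2$dataset$sorts)
  expect_identical(as.data.frame(g1$dataset$ratings),
                   as.data.frame(g2$dataset$ratings))
  # separate sub-streams: adding raters leaves the sorts untouched
  cfg_more <- synthetic_config(S = 15, K = 3, n_sorters = 5, seed = 42,
                               group_sizes = c(consumer = 40, provider = 1))
  g3 <- generate_dataset(cfg_more)
  expect_identical(g3$dataset$sorts, g1$dataset$sorts)
})

test_that("configuration invariants are enforced", {
  expect_error(synthetic_config(S = 10, K = 12), "K <= S")
  expect_error(synthetic_config(epsilon = 1.2), "probabilities")
  expect_error(synthetic_config(S = 10, K = 3, cluster_sizes = c(5, 5)),
               "cluster_sizes")
  expect_error(synthetic_config(group_sizes = c(patient = 5)),
               "consumer/provider/other")
  cfg <- synthetic_config(S = 10, K = 3)
  expect_equal(cfg$cluster_sizes, c(4L, 3L, 3L))
})

test_that("the noiseless limit reproduces the planted partition exactly", {
  cfg <- synthetic_config(S = 21, K = 7, n_sorters = 6, epsilon = 0,
                          merge_prob = 0, split_prob = 0, seed = 3)
  g <- generate_sorts(cfg)
  truth <- g$ground_truth$planted_partition
  for (s in g$sorts) {
    for (p in s$piles)
      expect_length(unique(truth[as.character(p$members)]), 1)
    expect_length(s$piles, 7)
  }
  # aggregate similarity is exactly N within clusters, 0 between
  st <- toy_statements(21)
  sim <- aggregate_similarity(g$sorts, st)
  same <- outer(truth, truth, `==`)
  expect_true(all(unclass(sim)[same] == 6L))
  expect_true(all(unclass(sim)[!same] == 0L))
})

test_that("full jitter erases the planted structure", {
  # epsilon = 1: every statement moves to a uniformly chosen different pile.
  # With K piles the analytic same-pile probability is 1/(K-1) for a planted
  # within pair and about (K-2)/(K-1)^2 for a between pair; at K = 7 the gap
  # is 1/36, far from the noiseless gap of 1.
  cfg <- synthetic_config(S = 21, K = 7, n_sorters = 150, epsilon = 1,
                          merge_prob = 0, split_prob = 0, seed = 5)
  g <- generate_sorts(cfg)
  sim <- aggregate_similarity(g$sorts, toy_statements(21))
  truth <- g$ground_truth$planted_partition
  same <- outer(truth, truth, `==`) & upper.tri(sim)
  diff <- (!outer(truth, truth, `==`)) & upper.tri(sim)
  within_rate <- mean(unclass(sim)[same]) / 150
  between_rate <- mean(unclass(sim)[diff]) / 150
  expect_lt(abs(within_rate - between_rate), 0.06)
  expect_equal(within_rate - between_rate, 1 / 36, tolerance = 0.9)
})

test_that("ratings discretize latent means by round-then-clip", {
  zero_noise <- synthetic_config(S = 6, K = 3, n_sorters = 2,
                                 statement_effect_sd = 0, rating_noise_sd = 0,
                                 group_sizes = c(consumer = 3),
                                 group_baselines = c(consumer = 4,
                                                     provider = 3.6,
                                                     other = 3.5),
                                 group_cluster_effects = matrix(
                                   0, 1, 3, dimnames = list("consumer", NULL)),
                                 seed = 2)
  g <- generate_dataset(zero_noise)
  expect_true(all(g$dataset$ratings$rating == 4L))

  ceiling_cfg <- synthetic_config(S = 6, K = 3, n_sorters = 2,
                                  statement_effect_sd = 0, rating_noise_sd = 0,
                                  group_sizes = c(consumer = 3),
                                  group_baselines = c(consumer = 9,
                                                      provider = 3.6,
                                                      other = 3.5),
                                  group_cluster_effects = matrix(
                                    0, 1, 3, dimnames = list("consumer", NULL)),
                                  seed = 2)
  g2 <- generate_dataset(ceiling_cfg)
  expect_true(all(g2$dataset$ratings$rating == 5L))
  expect_true(all(g2$ground_truth$planted_statement_means["consumer", ] == 9))
})

test_that("planted cluster-importance ordering survives sampling noise", {
  eff <- matrix(c(0.5, 0, -0.5), 1, 3, dimnames = list("consumer", NULL))
  hits <- vapply(1:200, function(s) {
    cfg <- synthetic_config(S = 9, K = 3, n_sorters = 2,
                            group_sizes = c(consumer = 20),
                            group_cluster_effects = eff,
                            statement_effect_sd = 0.1, rating_noise_sd = 0.5,
                            seed = s)
    g <- generate_sorts(cfg)
    r <- generate_ratings(cfg, g$ground_truth)
    sol <- as_solution(g$ground_truth$planted_partition)
    cs <- cluster_summary(sol, statement_means(r$ratings))
    identical(order(-cs$mean), 1:3)
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("rating means approach the planted latent means as raters grow", {
  rmse_at <- function(n) {
    cfg <- synthetic_config(S = 12, K = 3, n_sorters = 2,
                            group_sizes = c(consumer = n),
                            statement_effect_sd = 0.2, rating_noise_sd = 0.8,
                            seed = 77)
    g <- generate_sorts(cfg)
    r <- generate_ratings(cfg, g$ground_truth)
    sm <- statement_means(r$ratings, "consumer")
    latent <- r$ground_truth$planted_statement_means["consumer",
                                                     as.character(sm$statement_id)]
    sqrt(mean((sm$mean - latent)^2))
  }
  expect_lt(rmse_at(250), rmse_at(8))
})

test_that("the ARI matches brute-force pair counting and external oracles", {
  set.seed(88)
  for (rep in 1:15) {
    n <- sample(6:20, 1)
    a <- sample(1:4, n, replace = TRUE)
    b <- sample(1:4, n, replace = TRUE)
    expect_equal(adjusted_rand_index(a, b), brute_ari(a, b), tolerance = 1e-12)
    expect_equal(adjusted_rand_index(a, b), mclust::adjustedRandIndex(a, b),
                 tolerance = 1e-12)
  }
  expect_equal(adjusted_rand_index(c(1, 1, 2, 2), c(5, 5, 9, 9)), 1)
  # independent partitions score near zero on average
  set.seed(89)
  aris <- replicate(100, adjusted_rand_index(sample(1:4, 40, TRUE),
                                             sample(1:4, 40, TRUE)))
  expect_lt(abs(mean(aris)), 0.1)
})

test_that("noiseless recovery through the full pipeline is perfect", {
  cfg <- synthetic_config(S = 21, K = 7, n_sorters = 5, epsilon = 0,
                          merge_prob = 0, split_prob = 0, seed = 13)
  g <- generate_dataset(cfg)
  rr <- recovery_report(g$dataset, g$ground_truth, seed = 13, n_starts = 4)
  expect_equal(rr$ari, 1)
  expect_equal(rr$label_recovery_rate, 1)
})
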