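test_that("response simulation is deterministic and respects its config", {
  cfg <- ideation_sim_config(
    embedding = toy_embedding_config(3, 8, dimension = 15,
                                     within_cluster_spread = 0.1, seed = 2),
    n_participants = 12, fluency_min = 2, fluency_max = 6,
    switch_probability = 0.5, seed = 77)
  a <- simulate_responses(cfg)
  b <- simulate_responses(cfg)
  expect_identical(a$responses, b$responses)

  flu <- table(paste(a$responses$participant_id, a$responses$item_id))
  expect_true(all(flu >= 2 & flu <= 6))
  expect_equal(length(unique(a$responses$participant_id)), 12L)
})

test_that("switch probability 0 locks clusters; 1 forces a switch each step", {
  base <- toy_embedding_config(3, 8, dimension = 15,
                               within_cluster_spread = 0.1, seed = 2)
  frozen <- simulate_responses(ideation_sim_config(
    embedding = base, n_participants = 20, switch_probability = 0, seed = 5))
  by_cell <- split(frozen$responses$cluster,
                   paste(frozen$responses$participant_id,
                         frozen$responses$item_id))
  expect_true(all(vapply(by_cell, function(cl) length(unique(cl)) == 1L,
                         logical(1L))))

  always <- simulate_responses(ideation_sim_config(
    embedding = base, n_participants = 20, switch_probability = 1, seed = 5))
  by_cell2 <- split(always$responses$cluster,
                    paste(always$responses$participant_id,
                          always$responses$item_id))
  expect_true(all(vapply(by_cell2, function(cl) {
    length(cl) < 2L || all(cl[-1L] != cl[-length(cl)])
  }, logical(1L))))
})

test_that("realized switch frequency converges to switch_probability", {
  sim <- simulate_responses(ideation_sim_config(
    embedding = toy_embedding_config(4, 10, dimension = 20,
                                     within_cluster_spread = 0.1, seed = 3),
    n_participants = 150, fluency_min = 8, fluency_max = 12,
    switch_probability = 0.3, seed = 11))
  by_cell <- split(sim$responses$cluster,
                   paste(sim$responses$participant_id,
                         sim$responses$item_id))
  switches <- vapply(by_cell, function(cl) {
    c(sum(cl[-1L] != cl[-length(cl)]), length(cl) - 1L)
  }, numeric(2L))
  rate <- sum(switches[1L, ]) / sum(switches[2L, ])
  expect_equal(rate, 0.3, tolerance = 0.03)
})

test_that("mean flexibility rises with planted switch probability", {
  emb <- toy_embedding_config(4, 10, dimension = 20,
                              within_cluster_spread = 0.1, seed = 3)
  model <- make_toy_embeddings(emb)
  means <- vapply(c(0.1, 0.5, 0.9), function(sp) {
    sim <- simulate_responses(ideation_sim_config(
      embedding = emb, n_participants = 100, switch_probability = sp,
      seed = 19))
    mean(score_responses(sim$responses, model)$flex_mean, na.rm = TRUE)
  }, numeric(1L))
  expect_true(all(diff(means) > 0))
})

test_that("raising allowed fluency raises flex_sum but not flex_mean", {
  emb <- toy_embedding_config(4, 10, dimension = 20,
                              within_cluster_spread = 0.1, seed = 3)
  model <- make_toy_embeddings(emb)
  score_at <- function(fmin, fmax, divisor) {
    sim <- simulate_responses(ideation_sim_config(
      embedding = emb, n_participants = 120, fluency_min = fmin,
      fluency_max = fmax, switch_probability = 0.5, seed = 23))
    sc <- score_responses(sim$responses, model, mean_divisor = divisor)
    c(sum = mean(sc$flex_sum, na.rm = TRUE),
      mean = mean(sc$flex_mean, na.rm = TRUE))
  }
  lo <- score_at(3, 5, "fluency")
  hi <- score_at(9, 12, "fluency")
  # sum inflates mechanically (response count roughly triples)
  expect_gt(hi[["sum"]], 2 * lo[["sum"]])
  # the fluency-divided mean moves only by its mechanical (n-1)/n factor
  expect_lt(abs(hi[["mean"]] - lo[["mean"]]), 0.3 * lo[["mean"]])
  # per-pair expectation is fluency-free: the pairs-divided mean is stable
  lo_p <- score_at(3, 5, "pairs")
  hi_p <- score_at(9, 12, "pairs")
  expect_lt(abs(hi_p[["mean"]] - lo_p[["mean"]]), 0.05 * lo_p[["mean"]])
})

test_that("two-token responses average within-cluster tokens", {
  sim <- simulate_responses(ideation_sim_config(
    embedding = toy_embedding_config(2, 6, dimension = 10,
                                     within_cluster_spread = 0.1, seed = 2),
    n_participants = 5, tokens_per_response = 2, seed = 9))
  toks <- strsplit(sim$responses$response, " ", fixed = TRUE)
  expect_true(all(lengths(toks) == 2L))
  # both tokens share the planted cluster prefix
  expect_true(all(vapply(toks, function(t) {
    substr(t[[1L]], 1L, 2L) == substr(t[[2L]], 1L, 2L)
  }, logical(1L))))
})

test_that("factor-data simulation matches its implied covariance", {
  cfg0 <- factor_sim_config(rep(0, 4), n = 5000, seed = 41)
  dat0 <- simulate_factor_data(cfg0)
  cors <- cor(dat0)
  expect_true(all(abs(cors[upper.tri(cors)]) < 0.05))

  cfg <- factor_sim_config(rep(0.7, 6), n = 5000, seed = 42)
  dat <- simulate_factor_data(cfg)
  offdiag <- cor(dat)[upper.tri(diag(6))]
  expect_true(all(abs(offdiag - 0.49) < 0.05))

  expect_identical(simulate_factor_data(cfg), simulate_factor_data(cfg))

  big <- factor_sim_config(rep(0.6, 5), n = 20000, seed = 43)
  err <- max(abs(cov(simulate_factor_data(big)) - implied_covariance(big)))
  expect_lt(err, 0.05)
})

test_that("non-positive-definite implied covariance is rejected", {
  expect_error(factor_sim_config(c(1.2, 0.9, 0.8)), "residual variances")
  expect_error(
    implied_covariance(factor_sim_config(
      c(a = 0.9, b = 0.9), residual_variances = c(0.19, 0.19),
      residual_pairs = list(list(c("a", "b"), -1.9)))),
    "positive definite")
})
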