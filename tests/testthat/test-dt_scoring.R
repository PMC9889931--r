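test_that("semantic distance and angle follow the cosine geometry", {
  u <- c(0.3, 0.4)
  expect_equal(semantic_distance(u, u), 0)
  expect_equal(semantic_distance(c(1, 0), c(0, 1)), 1)
  expect_equal(semantic_distance(c(1, 0), c(-1, 0)), 2)
  expect_equal(semantic_distance(c(1, 0), c(sqrt(2) / 2, sqrt(2) / 2)),
               1 - cos(pi / 4), tolerance = 1e-12)
  expect_equal(round(semantic_distance(c(1, 0), c(sqrt(2) / 2, sqrt(2) / 2)), 5),
               0.29289)

  expect_equal(angle_degrees(u, u), 0)
  expect_equal(angle_degrees(c(1, 0), c(0, 1)), 90)
  expect_equal(angle_degrees(c(1, 0), c(sqrt(2) / 2, sqrt(2) / 2)), 45,
               tolerance = 1e-10)
  # distance = 1 - cos(angle) whenever both are defined
  set.seed(8)
  for (i in 1:20) {
    a <- rnorm(5); b <- rnorm(5)
    expect_equal(semantic_distance(a, b),
                 1 - cos(angle_degrees(a, b) * pi / 180),
                 tolerance = 1e-12)
  }
})

test_that("undefined vectors propagate through distances, never as zeros", {
  m <- model_from_vectors(list(cat = c(1, 0)))
  undef <- vectorize_response("zebra", m, stoplist = character(0L))
  def <- vectorize_response("cat", m)
  expect_true(is.na(semantic_distance(undef, def)))
  expect_true(is.na(angle_degrees(def, undef)))
})

test_that("distance matches a brute-force unit-vector oracle to 1e-12", {
  set.seed(33)
  for (i in 1:50) {
    a <- rnorm(8); a <- a / sqrt(sum(a^2))
    b <- rnorm(8); b <- b / sqrt(sum(b^2))
    expect_equal(semantic_distance(a, b), 1 - sum(a * b), tolerance = 1e-12)
  }
})

test_that("consecutive pairs link adjacent order indices, order preserved", {
  p <- consecutive_pairs(c(1L, 2L, 3L))
  expect_equal(p$first_order_index, c(1L, 2L))
  expect_equal(p$second_order_index, c(2L, 3L))
  expect_equal(nrow(consecutive_pairs(1L)), 0L)
  expect_equal(nrow(consecutive_pairs(1:5)), 4L)
  expect_equal(consecutive_pairs(c(3L, 1L, 2L))$first_order_index, c(1L, 2L))
  expect_error(consecutive_pairs(c(1L, 1L, 2L), "p9", "bottle"),
               "p9.*bottle")
})

test_that("item scoring reproduces the worked three-response example", {
  m <- model_from_vectors(worked_vectors)
  sc <- score_item(worked_responses, m, prompt_text = "alpha",
                   participant_id = "p1", item_id = "alpha")
  expect_equal(sc$fluency, 3L)
  expect_equal(sc$n_pairs_scored, 2L)
  expect_equal(sc$flex_sum, 0.6, tolerance = 1e-12)
  expect_equal(sc$flex_max, 0.4, tolerance = 1e-12)
  expect_equal(sc$flex_mean, 0.2, tolerance = 1e-12)  # sum / fluency
  # originality: prompt alpha -> distances 0, 0.2, 1
  expect_equal(sc$orig_sum, 1.2, tolerance = 1e-12)
  expect_equal(sc$orig_max, 1.0, tolerance = 1e-12)
  expect_equal(sc$orig_mean, 0.4, tolerance = 1e-12)

  # pairs divisor variant
  sc2 <- score_item(worked_responses, m, prompt_text = "alpha",
                    mean_divisor = "pairs")
  expect_equal(sc2$flex_mean, 0.3, tolerance = 1e-12)
})

test_that("identical responses give zero flexibility; single response none", {
  m <- model_from_vectors(worked_vectors)
  same <- data.frame(participant_id = "p", item_id = "i",
                     order_index = 1:4, response = "beta")
  sc <- score_item(same, m)
  expect_equal(sc$flex_sum, 0)
  expect_equal(sc$flex_mean, 0)
  expect_equal(sc$flex_max, 0)

  one <- data.frame(participant_id = "p", item_id = "i",
                    order_index = 1L, response = "beta")
  sc1 <- score_item(one, m)
  expect_equal(sc1$fluency, 1L)
  expect_true(is.na(sc1$flex_sum))
  expect_true(is.na(sc1$flex_mean))
})

test_that("appending a duplicate response fixes flex_sum, deflates flex_mean", {
  m <- model_from_vectors(worked_vectors)
  base <- worked_responses
  extended <- rbind(base, data.frame(participant_id = "p1",
                                     item_id = "alpha", order_index = 4L,
                                     response = "gamma"))
  s0 <- score_item(base, m)
  s1 <- score_item(extended, m)
  expect_equal(s1$fluency, s0$fluency + 1L)
  expect_equal(s1$flex_sum, s0$flex_sum, tolerance = 1e-12)
  expect_lt(s1$flex_mean, s0$flex_mean)
  expect_gte(s1$flex_max, max(0.2, 0.4) - 1e-12)
})

test_that("alternating clusters scores strictly higher flex_sum than blocked", {
  model <- make_toy_embeddings(toy_embedding_config(
    2, 5, dimension = 10, within_cluster_spread = 0.1, seed = 21))
  alternating <- data.frame(
    participant_id = "p", item_id = "c1_t1", order_index = 1:6,
    response = c("c1_t1", "c2_t1", "c1_t2", "c2_t2", "c1_t3", "c2_t3"))
  blocked <- data.frame(
    participant_id = "p", item_id = "c1_t1", order_index = 1:6,
    response = c("c1_t1", "c1_t2", "c1_t3", "c2_t1", "c2_t2", "c2_t3"))
  sa <- score_item(alternating, model)
  sb <- score_item(blocked, model)
  # brute-force oracle over the two sequences' pairs
  brute <- function(tokens) {
    v <- unclass(model)[tokens, ]
    sum(vapply(seq_len(nrow(v) - 1L), function(i) {
      1 - sum(v[i, ] * v[i + 1L, ]) /
        sqrt(sum(v[i, ]^2) * sum(v[i + 1L, ]^2))
    }, numeric(1L)))
  }
  expect_equal(sa$flex_sum, brute(alternating$response), tolerance = 1e-12)
  expect_equal(sb$flex_sum, brute(blocked$response), tolerance = 1e-12)
  expect_gt(sa$flex_sum, sb$flex_sum)
})

test_that("table scoring is invariant to input row order and undefined-aware", {
  model <- make_toy_embeddings(toy_embedding_config(
    2, 5, dimension = 10, within_cluster_spread = 0.1, seed = 21))
  sim <- simulate_responses(ideation_sim_config(
    embedding = toy_embedding_config(2, 5, dimension = 10,
                                     within_cluster_spread = 0.1, seed = 21),
    n_participants = 6, seed = 2))
  resp <- sim$responses
  set.seed(1)
  shuffled <- resp[sample(nrow(resp)), , drop = FALSE]
  s1 <- score_responses(resp, model)
  s2 <- score_responses(shuffled, model)
  expect_equal(s2, s1)

  # an OOV-only response still counts toward fluency but not pairs
  rr <- data.frame(participant_id = "p", item_id = "c1_t1",
                   order_index = 1:3,
                   response = c("c1_t1", "qqq", "c1_t2"))
  sc <- score_item(rr, model)
  expect_equal(sc$fluency, 3L)
  expect_equal(sc$n_pairs_scored, 0L)  # both pairs touch the undefined row
  expect_true(is.na(sc$flex_sum))
})

test_that("battery aggregation averages and maximizes across items", {
  scores <- data.frame(
    participant_id = "p1", item_id = c("a", "b"),
    fluency = c(3L, 5L), n_pairs_scored = c(2L, 4L),
    flex_sum = c(0.4, 1.0), flex_mean = c(0.2, 0.25),
    flex_max = c(0.3, 0.5),
    orig_sum = c(NA, 1), orig_mean = c(NA, 0.2), orig_max = c(NA, 0.6))
  b <- aggregate_battery(scores)
  expect_equal(b$fluency_mean_across_items, 4.0)
  expect_equal(b$fluency_max_across_items, 5L)
  expect_equal(b$flex_mean_across_items, 0.225)
  expect_equal(b$flex_max_across_items, 0.5)
  expect_equal(b$orig_mean_across_items, 0.2)  # undefined cells skipped

  ten <- data.frame(participant_id = "p", item_id = letters[1:10],
                    fluency = 1:10, n_pairs_scored = 0L,
                    flex_sum = NA_real_, flex_mean = NA_real_,
                    flex_max = NA_real_, orig_sum = NA_real_,
                    orig_mean = NA_real_, orig_max = NA_real_)
  b10 <- aggregate_battery(ten)
  expect_equal(b10$fluency_mean_across_items, 5.5)
  expect_equal(b10$fluency_max_across_items, 10L)
  expect_true(is.na(b10$flex_mean_across_items))

  dup <- ten; dup$item_id <- rep("a", 10L)
  expect_error(aggregate_battery(dup), "duplicate item")
})

test_that("response tables round-trip and reject bad structure", {
  p <- tempfile(fileext = ".csv")
  writeLines(c("participant_id,item_id,order_index,response",
               "p1,bottle,1,vase",
               "p1,bottle,2,musical instrument",
               "p2,bottle,1,  "), p)
  expect_warning(df <- read_responses(p), "empty response")
  expect_equal(nrow(df), 2L)
  out <- tempfile(fileext = ".csv")
  write_responses(df, out)
  df2 <- read_responses(out)
  expect_equal(df2, df)

  bad <- tempfile(fileext = ".csv")
  writeLines(c("participant_id,item_id,order_index,response",
               "p1,bottle,1,vase", "p1,bottle,1,drum"), bad)
  expect_error(read_responses(bad), "duplicate order_index")
})
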