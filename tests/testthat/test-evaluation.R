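test_that("single-member LOOCV scores the member's own choices with binomial SEM", {
  # perfect agent
  p <- manual_panel(c(0, 1, 0, 1), c(1, 1, 0, 0), truth = c(0, 1, 0, 1))
  res <- loocv(p, "a")
  expect_equal(res$accuracy, 1)
  expect_equal(res$sem, 0)

  # 100 observations, 50 correct: accuracy 0.5, SEM 0.05
  truth <- rep(0L, 100)
  choices <- rep(c(0L, 1L), 50)
  p2 <- manual_panel(choices, rep(0L, 100), truth = truth)
  res2 <- loocv(p2, "a")
  expect_equal(res2$accuracy, 0.5)
  expect_equal(res2$sem, 0.05)
  expect_equal(res2$n_evaluations, 100L)
})

test_that("accuracy and SEM recomputed from the stored flags match the summary", {
  p <- small_team_panel(14L)
  res <- loocv(p, team_spec(c("h", "m")))
  expect_equal(res$accuracy, mean(res$predictions$correct))
  expect_equal(res$sem, sqrt(res$accuracy * (1 - res$accuracy) / res$n_evaluations))
})

test_that("the held-out item never appears in the training fold", {
  p <- small_team_panel(15L, n_items = 10L)
  res <- loocv(p, team_spec(c("h", "m")), keep_folds = TRUE)
  folds <- attr(res, "folds")
  expect_equal(length(folds), 10L)
  for (f in folds) {
    expect_false(any(f$held %in% f$train_items))
    expect_setequal(c(f$held, f$train_items), names(p$truth))
  }
})

test_that("fully correlated identical members add nothing over one member", {
  # two agents with identical judgments on every item
  p0 <- small_team_panel(16L, n_items = 40L)
  h_rec <- p0$records[p0$records$agent_id == "h", ]
  h_rec <- h_rec[!duplicated(h_rec$item_id), ]
  twin <- h_rec
  twin$agent_id <- "h2"
  agents <- data.frame(agent_id = c("h", "h2"),
                       agent_type = "human_discrete",
                       rating_levels = 3L, stringsAsFactors = FALSE)
  p <- judgment_panel(rbind(h_rec, twin), p0$truth, agents, 2L)
  solo <- loocv(p, "h")
  duo <- loocv(p, team_spec(c("h", "h2")))
  expect_lt(abs(duo$accuracy - solo$accuracy), 2 * solo$sem + 1e-9)
})

test_that("Bayesian and majority combiners run through grouped CV with the guard", {
  p <- simulate_panel(panel_spec(
    30L, 2L,
    agents = list(
      agent_spec("h", "human_discrete", 0.66, shared_difficulty_loading = 0.3),
      agent_spec("s", "machine_scores", 0.72, shared_difficulty_loading = 0.3)),
    humans_per_item = c(2L, 3L), seed = 5L))
  res <- suppressWarnings(loocv(p, team_spec(c("h", "s"), combiner = "bayesian"),
                                n_folds = 3L, chains = 1L, warmup = 150L,
                                draws = 100L, seed = 2L, keep_folds = TRUE))
  expect_s3_class(res, "team_eval")
  expect_equal(res$accuracy, mean(res$predictions$correct))
  for (f in attr(res, "folds")) {
    expect_false(any(f$held %in% f$train_items))
  }
  maj <- loocv(p, team_spec(c("h", "s"), combiner = "majority"))
  expect_s3_class(maj, "team_eval")
  # two-member majority ties on every disagreement; ties are counted
  disagree <- sum(maj$predictions$predicted !=
                    p$records$chosen_label[build_feature_matrix(
                      p, team_spec(c("h", "s")))$observations$rec.h])
  expect_gte(maj$tie_count, disagree)
})

test_that("team enumeration covers all non-empty subsets with human tags", {
  agents <- data.frame(agent_id = c("h", "m1", "m2", "m3"),
                       agent_type = c("human_continuous", rep("machine_perplexity", 3)))
  teams <- enumerate_teams(agents)
  expect_length(teams, 15L)
  expect_length(enumerate_teams("solo"), 1L)
  expect_length(enumerate_teams(c("a", "b")), 3L)
  with_h <- vapply(teams, function(t) isTRUE(attr(t, "with_human")), logical(1))
  expect_equal(sum(with_h), 8L)  # human alone + human with each machine subset
  sizes <- vapply(teams, function(t) length(t$members), integer(1))
  expect_equal(as.integer(table(sizes)), c(4L, 6L, 4L, 1L))
})

test_that("shuffled predictions fall to chance and are seed-reproducible", {
  p <- small_team_panel(17L, n_items = 60L)
  base <- loocv(p, "m")
  s1 <- shuffle_control(p, "m", seed = 5L, result = base)
  s2 <- shuffle_control(p, "m", seed = 5L, result = base)
  expect_identical(s1$predictions$predicted, s2$predictions$predicted)
  expect_true(s1$shuffled)
  # marginals preserved, association destroyed
  expect_equal(sort(s1$predictions$predicted), sort(base$predictions$predicted))
})

test_that("Welch and paired comparisons match hand formulas and df patterns", {
  x <- c(0.71, 0.74, 0.78)
  y <- c(0.64, 0.69, 0.66)
  out <- compare_accuracies(x, y)
  hand <- welch_by_hand(x, y)
  expect_equal(out$statistic, hand$t, tolerance = 1e-12)
  expect_equal(out$df, hand$df, tolerance = 1e-12)

  # identical groups: t = 0, p = 1
  same <- compare_accuracies(c(0.6, 0.7, 0.8), c(0.6, 0.7, 0.8))
  expect_equal(same$statistic, 0)
  expect_equal(same$p.value, 1)

  # paired lists of length 3 give df = 2
  paired <- compare_accuracies(c(0.70, 0.72, 0.75), c(0.66, 0.69, 0.71),
                               paired = TRUE)
  expect_equal(paired$df, 2)

  expect_error(compare_accuracies(c(0.5, 0.5), c(0.5, 0.5)), "zero variance")
})

test_that("calibration curves: informative confidence yields a positive slope", {
  # agent whose confidence is exactly its correctness probability
  with_seed(23, {
    m <- 1000L
    conf <- runif(m)
    correct <- rbinom(m, 1L, conf)
  })
  items <- sprintf("i%04d", seq_len(1000L))
  rec <- data.frame(item_id = items, agent_id = "a",
                    chosen_label = ifelse(correct == 1L, 0L, 1L),
                    confidence = conf, stringsAsFactors = FALSE)
  agents <- data.frame(agent_id = "a", agent_type = "human_continuous",
                       rating_levels = NA_integer_)
  p <- judgment_panel(rec, stats::setNames(rep(0L, 1000L), items), agents, 2L)
  cc <- calibration_curve(p, "a", n_bins = 5L)
  expect_gt(cc$slope, 0)
  expect_gt(cc$slope_confidence, 0)
  expect_equal(sum(cc$bins$count), 1000L)
  expect_true(all(diff(cc$bins$mean_confidence) > 0))

  # confidence independent of correctness: slope within noise of zero
  p_ind <- p
  p_ind$records$confidence <- with_seed(24, runif(1000L))
  cc_ind <- calibration_curve(p_ind, "a", n_bins = 5L)
  expect_lt(abs(cc_ind$slope), 0.05)

  # constant confidence: single effective bin, slope 0, flagged
  p_const <- p
  p_const$records$confidence <- 0.5
  cc_const <- calibration_curve(p_const, "a", n_bins = 5L)
  expect_true(cc_const$degenerate)
  expect_equal(cc_const$slope, 0)
  expect_equal(nrow(cc_const$bins), 1L)
})

test_that("equal-count binning spreads the remainder over the lowest bins", {
  items <- sprintf("i%02d", 1:13)
  rec <- data.frame(item_id = items, agent_id = "a", chosen_label = 0L,
                    confidence = 1:13, stringsAsFactors = FALSE)
  agents <- data.frame(agent_id = "a", agent_type = "human_continuous",
                       rating_levels = NA_integer_)
  p <- judgment_panel(rec, stats::setNames(rep(0L, 13L), items), agents, 2L)
  cc <- calibration_curve(p, "a", n_bins = 5L)
  expect_equal(cc$bins$count, c(3L, 3L, 3L, 2L, 2L))
  expect_warning(calibration_curve(p, "a", n_bins = 20L), "bins")
})

test_that("item difficulty follows the per-type rules with larger = easier", {
  # perplexity agent: q(incorrect) - q(correct)
  rec <- data.frame(item_id = c("i1", "i2"), agent_id = "m",
                    chosen_label = c(0L, 1L), confidence = c(2, 1),
                    ppl_0 = c(10, 11), ppl_1 = c(12, 10),
                    stringsAsFactors = FALSE)
  agents <- data.frame(agent_id = "m", agent_type = "machine_perplexity",
                       rating_levels = NA_integer_)
  p <- judgment_panel(rec, c(i1 = 0L, i2 = 0L), agents, 2L)
  d <- item_difficulty(p, "m")
  expect_equal(unname(d["i1"]), 2)   # easy: wrong version clearly worse
  expect_equal(unname(d["i2"]), -1)  # hard: wrong version looks better

  # human: mean correctness per item (3 of 4 correct -> 0.75)
  rec_h <- data.frame(item_id = rep("i1", 4), agent_id = "h",
                      chosen_label = c(0L, 0L, 0L, 1L), confidence = 1,
                      stringsAsFactors = FALSE)
  agents_h <- data.frame(agent_id = "h", agent_type = "human_continuous",
                         rating_levels = NA_integer_)
  ph <- judgment_panel(rec_h, c(i1 = 0L), agents_h, 2L)
  expect_equal(unname(item_difficulty(ph, "h")), 0.75)

  # score agent: probability at the true label
  rec_s <- data.frame(item_id = c("i1", "i2"), agent_id = "s",
                      chosen_label = c(0L, 1L), confidence = c(0.9, 0.6),
                      score_0 = c(0.9, 0.4), score_1 = c(0.1, 0.6),
                      stringsAsFactors = FALSE)
  agents_s <- data.frame(agent_id = "s", agent_type = "machine_scores",
                         rating_levels = NA_integer_)
  ps <- judgment_panel(rec_s, c(i1 = 0L, i2 = 0L), agents_s, 2L)
  expect_equal(unname(item_difficulty(ps, "s")), c(0.9, 0.4))
})

test_that("diversity matrix: unit diagonal, reversed ranks give -1, NA when sparse", {
  p <- manual_panel(c(0, 0, 0), c(0, 0, 0), truth = c(0, 0, 0),
                    conf_a = c(1, 2, 3), conf_b = c(3, 2, 1))
  # craft opposite difficulty orderings via correctness patterns
  rec <- rbind(
    data.frame(item_id = rep(c("i1", "i2", "i3"), each = 4), agent_id = "a",
               chosen_label = c(0L, 0L, 0L, 0L, 0L, 0L, 0L, 1L, 0L, 1L, 1L, 1L),
               confidence = 1, stringsAsFactors = FALSE),
    data.frame(item_id = rep(c("i1", "i2", "i3"), each = 4), agent_id = "b",
               chosen_label = c(0L, 1L, 1L, 1L, 0L, 0L, 0L, 1L, 0L, 0L, 0L, 0L),
               confidence = 1, stringsAsFactors = FALSE))
  agents <- data.frame(agent_id = c("a", "b"), agent_type = "human_continuous",
                       rating_levels = NA_integer_)
  p <- judgment_panel(rec, c(i1 = 0L, i2 = 0L, i3 = 0L), agents, 2L)
  dm <- diversity_matrix(p)
  expect_equal(unname(diag(dm)), c(1, 1))
  expect_equal(dm["a", "b"], -1)  # difficulties (1, .75, .25) vs (.25, .75, 1)
  expect_equal(dm["a", "b"], dm["b", "a"])

  # fewer than 3 shared items: entry marked missing
  p2 <- p
  p2$records <- p2$records[!(p2$records$agent_id == "b" &
                               p2$records$item_id %in% c("i1", "i2")), ]
  expect_true(is.na(diversity_matrix(p2)["a", "b"]))
})

test_that("shared difficulty with independent noise lands in the expected band", {
  p <- simulate_panel(panel_spec(
    200L, 2L,
    agents = list(
      agent_spec("x", "machine_perplexity", 0.7, shared_difficulty_loading = 1),
      agent_spec("y", "machine_perplexity", 0.7, shared_difficulty_loading = 1)),
    seed = 33L))
  rho <- diversity_matrix(p)["x", "y"]
  expect_gt(rho, 0.4)
  expect_lt(rho, 0.95)
})
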