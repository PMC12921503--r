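test_that("ordered-logistic pmf matches direct CDF differences", {
  # symmetry at the breakpoint
  expect_equal(unname(ordered_logistic_pmf(0.3, 0.3, 1)), c(0.5, 0.5))
  # R = 3, c = (0, 1), delta = 1, score 0
  pl <- stats::plogis(1)
  expect_equal(unname(ordered_logistic_pmf(0, c(0, 1), 1)),
               c(0.5, pl - 0.5, 1 - pl))
  # normalization and stochastic ordering in the score
  sc <- seq(-2, 2, by = 0.25)
  pmf <- ordered_logistic_pmf(sc, c(-0.5, 0.4, 1.1), 0.3)
  expect_equal(unname(rowSums(pmf)), rep(1, length(sc)), tolerance = 1e-12)
  cdf_top <- pmf[, ncol(pmf)]
  expect_true(all(diff(cdf_top) >= 0))  # higher score, higher ratings
  expect_error(ordered_logistic_pmf(0, c(1, 0), 1), "increasing")
  expect_error(ordered_logistic_pmf(0, c(0, 1), -1), "positive")
})

test_that("quantile discretization bins evenly, reuses edges, is rank-based", {
  r <- discretize_confidence(1:100, R = 4L)
  expect_equal(as.integer(table(r)), rep(25L, 4L))
  expect_equal(unique(as.integer(r)[1:25]), 0L)
  expect_equal(unique(as.integer(r)[76:100]), 3L)
  # monotone transform leaves ratings unchanged
  r2 <- discretize_confidence(exp(1:100 / 10), R = 4L)
  expect_equal(as.integer(r2), as.integer(r))
  # edges reused on held-out values
  edges <- attr(r, "edges")
  expect_equal(as.integer(discretize_confidence(c(2, 60, 99), R = 4L,
                                                edges = edges)),
               c(0L, 2L, 3L))
  # degenerate: all equal collapses with a warning
  expect_warning(rd <- discretize_confidence(rep(3, 10), R = 3L), "collapsing")
  expect_true(all(as.integer(rd) == 0L))
})

test_that("the generative simulator honors its parameters and seed", {
  # a = b: correctness indicator has no effect, choices at chance
  par0 <- bayes_params(0.5, 0.5, 0.5, 0.5, 0.3, 0.3, 0,
                       cutpoints = c(0.4, 0.6), delta = 0.2)
  truth <- with_seed(1, sample(0:1, 1500, replace = TRUE))
  sim <- simulate_generative(par0, truth, seed = 2)
  expect_lt(abs(mean(sim$y == truth) - 0.5), 3 * sqrt(0.25 / 1500))

  # strong rho: human and machine item-level evidence strongly correlated
  par1 <- bayes_params(0.8, 0.2, 0.8, 0.2, 0.3, 0.3, 0.9,
                       cutpoints = c(0.3, 0.7), delta = 0.2)
  truth <- with_seed(3, sample(0:1, 500, replace = TRUE))
  sim1 <- simulate_generative(par1, truth, seed = 4)
  m_margin <- (sim1$scores[, 1] - sim1$scores[, 2]) * ifelse(truth == 0, 1, -1)
  h_correct <- as.numeric(sim1$y == truth)
  expect_gt(stats::cor(m_margin, h_correct, method = "spearman"), 0.25)
  # the machine margins alone recover the correct label most of the time
  expect_gt(mean(m_margin > 0), 0.85)

  # reproducibility
  sim_a <- simulate_generative(par1, truth, seed = 7)
  sim_b <- simulate_generative(par1, truth, seed = 7)
  expect_identical(sim_a, sim_b)
})

test_that("posterior sampling is seed-reproducible with diagnostics recorded", {
  par <- bayes_params(0.75, 0.25, 0.75, 0.25, 0.3, 0.3, 0.3,
                      cutpoints = c(0.35, 0.65), delta = 0.2)
  bd <- generative_bayes_data(par, 60L, seed = 21L)
  f1 <- suppressWarnings(fit_bayesian(bd, chains = 1L, warmup = 250L,
                                      draws = 150L, seed = 9L))
  f2 <- suppressWarnings(fit_bayesian(bd, chains = 1L, warmup = 250L,
                                      draws = 150L, seed = 9L))
  expect_identical(f1$draws, f2$draws)
  expect_true(all(is.finite(f1$diagnostics$rhat)))
  expect_named(f1$diagnostics$rhat,
               c("a_H", "b_H", "a_M", "b_M", "sigma_H", "sigma_M", "rho",
                 "c_1", "c_2", "delta"))
  expect_true(all(f1$draws[, "sigma_H"] > 0))
  expect_true(all(abs(f1$draws[, "rho"]) < 1))
  expect_true(all(f1$draws[, "c_2"] > f1$draws[, "c_1"]))
})

test_that("no-signal data concentrate the posterior of a - b near zero", {
  par0 <- bayes_params(0.5, 0.5, 0.5, 0.5, 0.3, 0.3, 0,
                       cutpoints = c(0.4, 0.6), delta = 0.2)
  bd <- generative_bayes_data(par0, 150L, seed = 31L)
  fit <- suppressWarnings(fit_bayesian(bd, chains = 1L, warmup = 600L,
                                       draws = 400L, seed = 11L))
  gap_M <- fit$draws[, "a_M"] - fit$draws[, "b_M"]
  expect_lt(abs(mean(gap_M)), 0.1)  # machine gap directly observed
})

test_that("prediction: uniform under no signal, naive-Bayes factorization at rho 0", {
  par0 <- bayes_params(0.5, 0.5, 0.5, 0.5, 0.3, 0.3, 0,
                       cutpoints = c(0.4, 0.6), delta = 0.2)
  bd <- generative_bayes_data(par0, 80L, seed = 41L)
  fit <- suppressWarnings(fit_bayesian(bd, chains = 1L, warmup = 300L,
                                       draws = 200L, seed = 12L))
  # force an exactly uninformative parameter draw
  fit$draws <- fit$draws[rep(1L, 4L), , drop = FALSE]
  fit$draws[, c("a_H", "b_H")] <- 0.5
  fit$draws[, c("a_M", "b_M")] <- 0.5
  fit$draws[, "rho"] <- 0
  pr <- predict(fit, list(scores = matrix(c(0.7, 0.3), 1L), y = 0L, r = 2L),
                n_draws = 4L)
  expect_equal(unname(pr[1, ]), c(0.5, 0.5), tolerance = 1e-9)

  # rho = 0: joint prediction equals the normalized product of the two
  # members' standalone evidences, computed on a single fixed draw
  fit$draws[, c("a_H", "a_M")] <- 0.75
  fit$draws[, c("b_H", "b_M")] <- 0.25
  obs <- list(scores = matrix(c(0.68, 0.35), 1L), y = 0L, r = 1L)
  pr_joint <- predict(fit, obs, n_draws = 1L, gh_nodes = 24L)

  d1 <- fit$draws[1L, ]
  p <- list(a_H = 0.75, b_H = 0.25, a_M = 0.75, b_M = 0.25,
            sigma_H = d1[["sigma_H"]], sigma_M = d1[["sigma_M"]], rho = 0,
            cutpoints = unname(d1[c("c_1", "c_2")]), delta = d1[["delta"]],
            tau = fit$config$tau)
  gh <- teamjudge:::make_gh_grid(24L)
  lik_m <- function(z) {
    mu <- p$b_M + (p$a_M - p$b_M) * (c(0, 1) == z)
    prod(stats::dnorm(obs$scores[1, ], mu, p$sigma_M))
  }
  lik_h <- function(z) {
    mu <- p$b_H + (p$a_H - p$b_H) * (c(0, 1) == z)
    P0 <- mu[1] + p$sigma_H * gh$x0
    P1 <- mu[2] + p$sigma_H * gh$x1
    w0 <- stats::plogis((P0 - P1) / p$tau)
    pmf <- stats::plogis((p$cutpoints[2] - P0) / p$delta) -
      stats::plogis((p$cutpoints[1] - P0) / p$delta)
    sum(gh$w * w0 * pmf)  # y = 0, r = 1
  }
  prod_ev <- c(lik_m(0) * lik_h(0), lik_m(1) * lik_h(1))
  expect_equal(unname(pr_joint[1, ]), prod_ev / sum(prod_ev), tolerance = 1e-6)
})

test_that("prediction is symmetric under relabeling the two versions", {
  par <- bayes_params(0.75, 0.25, 0.78, 0.22, 0.35, 0.3, 0.25,
                      cutpoints = c(0.35, 0.65), delta = 0.2)
  bd <- generative_bayes_data(par, 100L, seed = 51L)
  fit <- suppressWarnings(fit_bayesian(bd, chains = 1L, warmup = 400L,
                                       draws = 200L, seed = 13L))
  obs <- list(scores = matrix(c(0.71, 0.30), 1L), y = 0L, r = 2L)
  obs_sw <- list(scores = matrix(c(0.30, 0.71), 1L), y = 1L, r = 2L)
  pr <- predict(fit, obs, n_draws = 50L)
  pr_sw <- predict(fit, obs_sw, n_draws = 50L)
  expect_equal(unname(pr[1, ]), unname(rev(pr_sw[1, ])), tolerance = 1e-9)
})

test_that("agreement with high confidence beats either standalone evidence", {
  par <- bayes_params(0.75, 0.25, 0.75, 0.25, 0.3, 0.3, 0.2,
                      cutpoints = c(0.35, 0.65), delta = 0.2)
  bd <- generative_bayes_data(par, 120L, seed = 61L)
  fit <- suppressWarnings(fit_bayesian(bd, chains = 1L, warmup = 400L,
                                       draws = 250L, seed = 14L))
  # both members confidently favor class 0
  joint <- predict(fit, list(scores = matrix(c(0.8, 0.2), 1L), y = 0L, r = 2L),
                   n_draws = 50L)[1, 1]
  # machine alone: neutral human signals carry no information either way
  m_only <- predict(fit, list(scores = matrix(c(0.8, 0.2), 1L), y = 0L, r = 0L),
                    n_draws = 50L)[1, 1]
  h_only <- predict(fit, list(scores = matrix(c(0.5, 0.5), 1L), y = 0L, r = 2L),
                    n_draws = 50L)[1, 1]
  expect_gt(joint, m_only)
  expect_gt(joint, h_only)
})

test_that("posterior predictive re-simulation reproduces human accuracy and ratings", {
  par <- bayes_params(0.75, 0.25, 0.75, 0.25, 0.35, 0.3, 0.3,
                      cutpoints = c(0.3, 0.7), delta = 0.2)
  bd <- generative_bayes_data(par, 200L, seed = 71L)
  fit <- suppressWarnings(fit_bayesian(bd, chains = 1L, warmup = 800L,
                                       draws = 500L, seed = 15L))
  pm <- coef(fit)
  par_hat <- bayes_params(pm[["a_H"]], pm[["b_H"]], pm[["a_M"]], pm[["b_M"]],
                          pm[["sigma_H"]], pm[["sigma_M"]], pm[["rho"]],
                          cutpoints = unname(pm[c("c_1", "c_2")]),
                          delta = pm[["delta"]])
  n_sim <- 4000L
  truth_sim <- with_seed(16, sample(0:1, n_sim, replace = TRUE))
  sim <- simulate_generative(par_hat, truth_sim, seed = 17L)

  acc_dat <- mean(bd$y == bd$z)
  acc_sim <- mean(sim$y == truth_sim)
  se <- sqrt(acc_dat * (1 - acc_dat) * (1 / length(bd$y) + 1 / n_sim))
  expect_lt(abs(acc_sim - acc_dat), 3 * se)

  for (k in 0:2) {
    p_dat <- mean(bd$r == k)
    p_sim <- mean(sim$r == k)
    se_k <- sqrt(p_dat * (1 - p_dat) * (1 / length(bd$r) + 1 / n_sim))
    expect_lt(abs(p_sim - p_dat), 3 * max(se_k, 1e-3))
  }
})

test_that("Bayesian team beats each member on calibrated, diverse panels", {
  par <- bayes_params(0.7, 0.3, 0.72, 0.28, 0.35, 0.3, 0.2,
                      cutpoints = c(0.35, 0.65), delta = 0.2)
  margins <- sapply(1:3, function(sd) {
    bd <- generative_bayes_data(par, 250L, seed = sd)
    tr <- 1:150
    te <- 151:250
    fit <- suppressWarnings(fit_bayesian(subset_bayes_data(bd, tr), chains = 1L,
                                         warmup = 800L, draws = 500L, seed = sd))
    bte <- subset_bayes_data(bd, te)
    prob <- predict(fit, bte, n_draws = 80L)
    pred <- max.col(prob) - 1L
    zt <- bte$z[bte$item_of]
    mch <- max.col(bte$scores) - 1L
    c(team = mean(pred == zt), human = mean(bte$y == zt),
      machine = mean(mch == bte$z))
  })
  expect_true(all(margins["team", ] >= margins["machine", ]))
  expect_true(all(margins["team", ] > margins["human", ]))
  expect_gt(mean(margins["team", ]), mean(margins["machine", ]))
})
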