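# Independent oracles and small hand-built fixtures.

# Generic-optimizer maximization of the penalized binary logistic
# likelihood, written independently of the package's Newton fitter.
oracle_logit_binary <- function(fm, y01, ridge) {
  X <- fm$X[, 1L, , drop = FALSE]
  dim(X) <- c(dim(fm$X)[1L], dim(fm$X)[3L])
  D <- cbind(1, X)
  if (!is.null(fm$extras)) D <- cbind(D, fm$extras)
  nll <- function(b) {
    eta <- drop(D %*% b)
    lse <- ifelse(eta > 0, eta + log1p(exp(-eta)), log1p(exp(eta)))
    -(sum(y01 * eta - lse) - 0.5 * ridge * sum(b[-1L]^2))
  }
  gr <- function(b) {
    p <- 1 / (1 + exp(-drop(D %*% b)))
    -(drop(crossprod(D, y01 - p)) - c(0, rep(ridge, ncol(D) - 1L)) * b)
  }
  stats::optim(rep(0, ncol(D)), nll, gr, method = "BFGS",
               control = list(maxit = 2000, reltol = 1e-14))$par
}

# conditional-logit negative log-likelihood maximized by a generic
# optimizer with numeric derivatives (multiclass oracle)
oracle_logit_multiclass <- function(fm, z, ridge) {
  X <- fm$X
  K <- dim(X)[3L]
  nll <- function(b) {
    evid <- matrix(0, dim(X)[1L], dim(X)[2L])
    for (k in seq_len(K)) evid <- evid + b[k] * X[, , k]
    -sum(evid[cbind(seq_len(nrow(evid)), z + 1L)] -
           log(rowSums(exp(evid)))) + 0.5 * ridge * sum(b^2)
  }
  stats::optim(rep(0, K), nll, method = "Nelder-Mead",
               control = list(maxit = 5000, reltol = 1e-14))$par
}

# textbook Welch statistic, hand formula
welch_by_hand <- function(x, y) {
  vx <- var(x) / length(x)
  vy <- var(y) / length(y)
  t <- (mean(x) - mean(y)) / sqrt(vx + vy)
  df <- (vx + vy)^2 / (vx^2 / (length(x) - 1) + vy^2 / (length(y) - 1))
  list(t = t, df = df)
}

# two-agent binary panel with judgments given explicitly
manual_panel <- function(choices_a, choices_b, truth,
                         conf_a = rep(1, length(choices_a)),
                         conf_b = rep(1, length(choices_b)),
                         n_classes = 2L) {
  items <- sprintf("i%02d", seq_along(truth))
  rec <- rbind(
    data.frame(item_id = items, agent_id = "a", chosen_label = choices_a,
               confidence = conf_a, stringsAsFactors = FALSE),
    data.frame(item_id = items, agent_id = "b", chosen_label = choices_b,
               confidence = conf_b, stringsAsFactors = FALSE)
  )
  agents <- data.frame(agent_id = c("a", "b"),
                       agent_type = "human_continuous",
                       rating_levels = NA_integer_, stringsAsFactors = FALSE)
  judgment_panel(rec, stats::setNames(as.integer(truth), items), agents,
                 n_classes)
}

# small two-agent panel from the generator, used in several places
small_team_panel <- function(seed, n_items = 12L) {
  simulate_panel(panel_spec(
    n_items, 2L,
    agents = list(
      agent_spec("h", "human_discrete", 0.65, shared_difficulty_loading = 0.3),
      agent_spec("m", "machine_perplexity", 0.7, shared_difficulty_loading = 0.3)),
    humans_per_item = c(1L, 2L), seed = seed))
}

# bayes_data straight from the generative model (model-consistent scores)
generative_bayes_data <- function(params, n_items, seed) {
  truth <- with_seed(seed, sample(0:1, n_items, replace = TRUE))
  sim <- simulate_generative(params, truth, seed = seed + 50L)
  structure(list(scores = sim$scores, z = truth,
                 item_ids = as.character(seq_len(n_items)),
                 item_of = seq_len(n_items), y = sim$y, r = sim$r,
                 R = length(params$cutpoints) + 1L, edges = NULL,
                 human = "h", machine = "m"),
            class = "bayes_data")
}

with_seed <- teamjudge:::with_seed
subset_bayes_data <- teamjudge:::subset_bayes_data
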