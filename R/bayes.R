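# Two-member Bayesian combination model.
#
# Latent probability scores for the human and the machine are correlated
# bivariate normals per item and class: the mean is b_k when the class is
# not the true label and a_k when it is, with member scales sigma_H,
# sigma_M and correlation rho_HM. The machine's latent scores are matched
# to its empirical probability scores; the human's are latent and generate
# the observed choice through a temperature softmax (tau small, so the
# choice is nearly the argmax of the latent scores) and the observed
# ordinal confidence rating through an ordered-logistic likelihood with
# increasing breakpoints c and sharpness delta. Posterior inference runs an
# adaptive random-walk Metropolis sampler on the marginal likelihood, with
# the human latent scores integrated out exactly by Gauss-Hermite
# quadrature (the integral is 2-dimensional for binary panels, the model's
# published setting).

#' Parameters of the Bayesian combination model
#'
#' @param a_H,a_M latent score mean when the class is the true label.
#' @param b_H,b_M latent score mean when it is not (`a > b` for
#'   identifiable fits: correctness raises the latent mean).
#' @param sigma_H,sigma_M positive member scales.
#' @param rho correlation between the two members' latent scores, in
#'   (-1, 1).
#' @param cutpoints strictly increasing ordered-logit breakpoints (length
#'   `R - 1`).
#' @param delta positive ordered-logit sharpness (scale divisor).
#' @param tau positive softmax temperature for the choice likelihood
#'   (small: the choice is nearly deterministic in the latent scores).
#' @param n_classes number of classes (the fitted model supports 2).
#' @return Object of class `bayes_params`.
#' @export
bayes_params <- function(a_H, b_H, a_M, b_M, sigma_H, sigma_M, rho,
                         cutpoints, delta, tau = 0.05, n_classes = 2L) {
  if (sigma_H <= 0 || sigma_M <= 0) stop_ctx("sigma must be positive")
  if (abs(rho) >= 1) stop_ctx("rho must lie in (-1, 1)")
  if (is.unsorted(cutpoints, strictly = TRUE)) {
    stop_ctx("cutpoints must be strictly increasing")
  }
  if (delta <= 0) stop_ctx("delta must be positive")
  if (tau <= 0) stop_ctx("tau must be positive")
  structure(list(a_H = a_H, b_H = b_H, a_M = a_M, b_M = b_M,
                 sigma_H = sigma_H, sigma_M = sigma_M, rho = rho,
                 cutpoints = cutpoints, delta = delta, tau = tau,
                 n_classes = as.integer(n_classes)),
            class = "bayes_params")
}

#' Ordered-logistic rating probabilities
#'
#' Cumulative parameterization `P(r <= k) = logistic((c_k - score) / delta)`
#' over ratings `0..R-1`; the distribution is stochastically increasing in
#' the score, and `delta` acts as an inverse-sharpness divisor.
#'
#' @param score latent score(s).
#' @param cutpoints strictly increasing breakpoints, length `R - 1`.
#' @param delta positive sharpness divisor.
#' @return `length(score) x R` matrix of probabilities (rows sum to 1); a
#'   plain vector for a single score.
#' @export
ordered_logistic_pmf <- function(score, cutpoints, delta) {
  if (is.unsorted(cutpoints, strictly = TRUE)) {
    stop_ctx("cutpoints must be strictly increasing")
  }
  if (delta <= 0) stop_ctx("delta must be positive")
  Fk <- vapply(cutpoints, function(ck) stats::plogis((ck - score) / delta),
               numeric(length(score)))
  Fk <- matrix(Fk, nrow = length(score))
  pmf <- cbind(Fk, 1) - cbind(0, Fk)
  colnames(pmf) <- paste0("r", seq_len(ncol(pmf)) - 1L)
  if (length(score) == 1L) drop(pmf) else pmf
}

#' Discretize continuous confidences into ordinal ratings
#'
#' Empirical-quantile binning into `R` ratings `0..R-1`, computed on
#' training values only; the bin edges are returned (attribute `"edges"`)
#' for reuse on held-out observations. Rank-based, hence invariant to
#' monotone transforms of the values. With fewer distinct values than bins
#' the scale collapses to the feasible number of bins with a warning.
#'
#' @param values non-negative confidences.
#' @param R number of rating levels (`>= 2`).
#' @param edges optional previously computed edges (then no recomputation).
#' @return Integer ratings in `0..R-1` with attribute `"edges"`.
#' @export
discretize_confidence <- function(values, R = 3L, edges = NULL) {
  R <- as.integer(R)
  if (R < 2L) stop_ctx("R must be >= 2")
  if (is.null(edges)) {
    if (length(unique(values)) < R) {
      warning("fewer distinct values than rating bins; collapsing the scale",
              call. = FALSE)
    }
    edges <- unique(stats::quantile(values, probs = seq_len(R - 1L) / R,
                                    names = FALSE, type = 7))
  }
  ratings <- findInterval(values, edges, left.open = TRUE)
  structure(as.integer(ratings), edges = edges)
}

# ---- data extraction ------------------------------------------------------

machine_scores_of <- function(panel, member, rec_idx) {
  type <- agent_type_of(panel, member)
  rec <- panel$records[rec_idx, , drop = FALSE]
  if (type == "machine_scores") {
    sc <- score_cols(panel)
    if (is.null(sc)) stop_ctx("panel has no score columns")
    as.matrix(rec[, sc, drop = FALSE])
  } else if (type == "machine_perplexity") {
    pc <- ppl_cols(panel)
    if (is.null(pc)) stop_ctx("panel has no perplexity columns")
    t(apply(as.matrix(rec[, pc, drop = FALSE]), 1L, perplexity_to_scores))
  } else {
    stop_ctx("member ", member, " is not a machine agent")
  }
}

#' Assemble the data the Bayesian combiner consumes
#'
#' Identifies the human member (providing choices `y` and ratings `r`) and
#' the machine member (providing per-class probability scores, converting
#' perplexities via `Softmax(-q)` when needed) of a two-member team, and
#' pairs them per observation. Continuous human confidences are discretized
#' into `R` quantile bins (edges kept for held-out reuse).
#'
#' @param panel a [judgment_panel].
#' @param team a two-member [team_spec].
#' @param observations optional pairing from [pair_observations()].
#' @param R rating levels used when the human confidence is continuous.
#' @return Object of class `bayes_data`.
#' @export
bayes_data_from_panel <- function(panel, team, observations = NULL, R = 3L) {
  team <- as_team_spec(team, combiner = "bayesian")
  if (length(team$members) != 2L) {
    stop_ctx("the Bayesian combiner requires exactly two members")
  }
  if (panel$n_classes != 2L) {
    stop_ctx("the Bayesian combiner supports binary panels (L = 2); ",
             "use the logistic combiner for multiclass teams")
  }
  types <- vapply(team$members, function(m) agent_type_of(panel, m), character(1))
  hi <- which(startsWith(types, "human"))
  mi <- which(startsWith(types, "machine"))
  if (length(hi) != 1L || length(mi) != 1L) {
    stop_ctx("need one human member (y, r) and one machine member (scores)")
  }
  human <- team$members[hi]
  machine <- team$members[mi]
  if (is.null(observations)) observations <- pair_observations(panel, team$members)

  hrec_idx <- observations[[paste0("rec.", human)]]
  mrec_idx <- observations[[paste0("rec.", machine)]]
  item_ids <- unique(observations$item_id)
  item_of <- match(observations$item_id, item_ids)
  first <- !duplicated(item_of)
  scores <- machine_scores_of(panel, machine, mrec_idx[first])[order(item_of[first]), ,
                                                               drop = FALSE]
  z <- unname(panel$truth[item_ids])
  y <- panel$records$chosen_label[hrec_idx]
  conf <- panel$records$confidence[hrec_idx]
  htype <- agent_type_of(panel, human)
  if (htype == "human_discrete") {
    Rh <- panel$agents$rating_levels[match(human, panel$agents$agent_id)]
    r <- as.integer(conf)
    edges <- NULL
  } else {
    Rh <- R
    r <- discretize_confidence(conf, Rh)
    edges <- attr(r, "edges")
    r <- as.integer(r)
  }
  structure(list(scores = scores, z = z, item_ids = item_ids,
                 item_of = item_of, y = as.integer(y), r = r,
                 R = as.integer(Rh), edges = edges,
                 human = human, machine = machine),
            class = "bayes_data")
}

subset_bayes_data <- function(bd, obs_idx) {
  keep_items <- sort(unique(bd$item_of[obs_idx]))
  structure(list(scores = bd$scores[keep_items, , drop = FALSE],
                 z = bd$z[keep_items],
                 item_ids = bd$item_ids[keep_items],
                 item_of = match(bd$item_of[obs_idx], keep_items),
                 y = bd$y[obs_idx], r = bd$r[obs_idx],
                 R = bd$R, edges = bd$edges,
                 human = bd$human, machine = bd$machine),
            class = "bayes_data")
}

# ---- parameter transforms -------------------------------------------------

# unconstrained vector <-> natural parameters; R = rating levels
theta_to_params <- function(theta, R, tau) {
  # The likelihood is invariant to a common shift of (a_H, b_H, c): the
  # choice depends on latent differences and the rating on the latent
  # relative to the breakpoints. Sampling the human location and gap as
  # separate coordinates, with the cutpoints as ordered offsets from b_H,
  # confines that flat direction to the single location coordinate (where
  # only the prior acts), which the adaptive proposal handles well.
  a_H <- theta[1L] + theta[2L] / 2
  b_H <- theta[1L] - theta[2L] / 2
  cut_raw <- theta[7L + seq_len(R - 1L)]
  cutp <- b_H + cumsum(c(cut_raw[1L], exp(cut_raw[-1L])))
  list(a_H = a_H, b_H = b_H, a_M = theta[3L], b_M = theta[4L],
       sigma_H = exp(theta[5L]), sigma_M = exp(theta[6L]),
       rho = tanh(theta[7L]), cutpoints = cutp,
       delta = exp(theta[7L + R]), tau = tau)
}

theta_names <- function(R) {
  c("a_H", "b_H", "a_M", "b_M", "sigma_H", "sigma_M", "rho",
    paste0("c_", seq_len(R - 1L)), "delta")
}

draws_natural <- function(theta_mat, R, tau) {
  out <- t(apply(theta_mat, 1L, function(th) {
    p <- theta_to_params(th, R, tau)
    c(p$a_H, p$b_H, p$a_M, p$b_M, p$sigma_H, p$sigma_M, p$rho, p$cutpoints,
      p$delta)
  }))
  colnames(out) <- theta_names(R)
  out
}

log_prior <- function(theta, R) {
  # a, b ~ N(0.5, 1); sigma, delta ~ HalfNormal(1) with log-scale Jacobian;
  # rho ~ U(-1, 1) with atanh Jacobian; cutpoints via ordered transform of
  # N(0, 2) increments.
  a_H <- theta[1L] + theta[2L] / 2
  b_H <- theta[1L] - theta[2L] / 2
  # priors act on the natural a, b scale; the (location, gap) map is linear
  # with constant Jacobian
  lp <- sum(stats::dnorm(c(a_H, b_H, theta[3L], theta[4L]), 0.5, 1, log = TRUE))
  for (i in c(5L, 6L, 7L + R)) {
    s <- exp(theta[i])
    lp <- lp + stats::dnorm(s, 0, 1, log = TRUE) + log(2) + theta[i]
  }
  rho <- tanh(theta[7L])
  lp <- lp + log(0.5) + log1p(-rho^2)
  lp + sum(stats::dnorm(theta[7L + seq_len(R - 1L)], 0, 2, log = TRUE))
}

# human-part likelihood pieces on a Gauss-Hermite pair grid
bayes_loglik <- function(theta, bd, tau, gh) {
  p <- theta_to_params(theta, bd$R, tau)
  if (p$delta < 1e-8 || p$sigma_H < 1e-8 || p$sigma_M < 1e-8) return(-Inf)
  n_items <- nrow(bd$scores)
  z <- bd$z
  # per item and class means
  mu_M0 <- p$b_M + (p$a_M - p$b_M) * (z == 0L)
  mu_M1 <- p$b_M + (p$a_M - p$b_M) * (z == 1L)
  mu_H0 <- p$b_H + (p$a_H - p$b_H) * (z == 0L)
  mu_H1 <- p$b_H + (p$a_H - p$b_H) * (z == 1L)

  ll_machine <- sum(stats::dnorm(bd$scores[, 1L], mu_M0, p$sigma_M, log = TRUE) +
                      stats::dnorm(bd$scores[, 2L], mu_M1, p$sigma_M, log = TRUE))
  if (!is.finite(ll_machine)) return(-Inf)

  # conditional human latent means given the observed machine scores
  slope <- p$rho * p$sigma_H / p$sigma_M
  m0 <- mu_H0 + slope * (bd$scores[, 1L] - mu_M0)
  m1 <- mu_H1 + slope * (bd$scores[, 2L] - mu_M1)
  s <- p$sigma_H * sqrt(1 - p$rho^2)

  # item x gridpoint latent values
  P0 <- outer(m0, s * gh$x0, `+`)
  P1 <- outer(m1, s * gh$x1, `+`)
  W0 <- stats::plogis((P0 - P1) / p$tau)  # P(choose class 0 | latents)

  io <- bd$item_of
  SEL <- W0[io, , drop = FALSE]
  y1 <- bd$y == 1L
  SEL[y1, ] <- 1 - SEL[y1, ]
  PY <- P0[io, , drop = FALSE]
  PY[y1, ] <- P1[io, , drop = FALSE][y1, ]

  # ordered-logistic pmf of the observed rating at the chosen-class latent
  Rr <- bd$R
  PMF <- matrix(0, nrow(PY), ncol(PY))
  Fprev <- matrix(0, nrow(PY), ncol(PY))
  for (k in seq_len(Rr)) {
    Fk <- if (k < Rr) stats::plogis((p$cutpoints[k] - PY) / p$delta) else 1
    rows <- bd$r == (k - 1L)
    if (any(rows)) {
      PMF[rows, ] <- (if (is.matrix(Fk)) Fk[rows, , drop = FALSE] else 1) -
        Fprev[rows, , drop = FALSE]
    }
    if (k < Rr) Fprev <- Fk
  }

  lik <- drop((SEL * PMF) %*% gh$w)
  ll_machine + sum(log(pmax(lik, 1e-300)))
}

make_gh_grid <- function(gh_nodes) {
  gh <- gh_normal(gh_nodes)
  grid <- expand.grid(a = seq_len(gh_nodes), b = seq_len(gh_nodes))
  list(x0 = gh$x[grid$a], x1 = gh$x[grid$b], w = gh$w[grid$a] * gh$w[grid$b])
}

# ---- adaptive random-walk Metropolis --------------------------------------

amh_chain <- function(lp_fun, init, warmup, draws, seed) {
  with_seed(seed, {
    d <- length(init)
    theta <- init
    lp <- lp_fun(theta)
    if (!is.finite(lp)) stop_ctx("non-finite log-posterior at the initial point")
    lambda <- 2.38 / sqrt(d)
    Sig_chol <- diag(0.05, d)
    hist_mat <- matrix(0, warmup, d)
    out <- matrix(0, draws, d)
    accepts <- 0L
    total <- warmup + draws
    for (t in seq_len(total)) {
      prop <- theta + lambda * drop(Sig_chol %*% stats::rnorm(d))
      lp_prop <- lp_fun(prop)
      acc <- is.finite(lp_prop) && log(stats::runif(1)) < lp_prop - lp
      if (acc) { theta <- prop; lp <- lp_prop }
      if (t <= warmup) {
        hist_mat[t, ] <- theta
        gam <- min(0.25, 2 / sqrt(t))
        lambda <- lambda * exp(gam * ((if (acc) 1 else 0) - 0.234))
        if (t >= 100L && t %% 50L == 0L) {
          S <- stats::cov(hist_mat[seq_len(t), , drop = FALSE]) + diag(1e-8, d)
          ch <- tryCatch(chol(S), error = function(e) NULL)
          if (!is.null(ch)) Sig_chol <- t(ch)
        }
      } else {
        out[t - warmup, ] <- theta
        if (acc) accepts <- accepts + 1L
      }
    }
    list(draws = out, accept_rate = accepts / draws)
  })
}

split_rhat <- function(chains) {
  # chains: list of draws matrices; split each in half, classic R-hat
  halves <- list()
  for (ch in chains) {
    n <- nrow(ch)
    h <- n %/% 2L
    halves <- c(halves, list(ch[seq_len(h), , drop = FALSE],
                             ch[(n - h + 1L):n, , drop = FALSE]))
  }
  m <- length(halves)
  n <- nrow(halves[[1]])
  d <- ncol(halves[[1]])
  rhat <- numeric(d)
  for (j in seq_len(d)) {
    means <- vapply(halves, function(h) mean(h[, j]), numeric(1))
    vars <- vapply(halves, function(h) stats::var(h[, j]), numeric(1))
    W <- mean(vars)
    B <- n * stats::var(means)
    rhat[j] <- if (W <= 0) 1 else sqrt(((n - 1) / n * W + B / n) / W)
  }
  rhat
}

#' Fit the two-member Bayesian combination model
#'
#' Posterior sampling of the model parameters (`a_H`, `b_H`, `a_M`, `b_M`,
#' `sigma_H`, `sigma_M`, `rho`, ordered-logit breakpoints `c`, sharpness
#' `delta`; temperature `tau` fixed) by adaptive random-walk Metropolis on
#' the marginal likelihood, with the human latent scores integrated out by
#' Gauss-Hermite quadrature. Ground-truth labels of the training items are
#' part of the data. Seed-reproducible; split-R-hat and acceptance-rate
#' diagnostics are recorded, and a fit with any R-hat above 1.05 is flagged
#' (and still returned).
#'
#' @param x a [judgment_panel] (with `team` naming one human and one
#'   machine member) or a prepared `bayes_data` object.
#' @param team two-member [team_spec] (panel interface only).
#' @param R rating levels used to discretize continuous confidences.
#' @param tau fixed softmax temperature of the choice likelihood.
#' @param chains,warmup,draws sampler size (total kept draws =
#'   `chains * draws`).
#' @param gh_nodes Gauss-Hermite nodes per latent dimension.
#' @param seed integer seed.
#' @param ... passed between methods.
#' @return Object of class `bayes_combiner`: natural-scale posterior
#'   `draws` matrix, `diagnostics` (`rhat`, `accept_rate`, `converged`),
#'   and the configuration echo.
#' @export
fit_bayesian <- function(x, ...) UseMethod("fit_bayesian")

#' @rdname fit_bayesian
#' @export
fit_bayesian.judgment_panel <- function(x, team, R = 3L, ...) {
  bd <- bayes_data_from_panel(x, team, R = R)
  fit_bayesian(bd, ...)
}

#' @rdname fit_bayesian
#' @export
fit_bayesian.bayes_data <- function(x, tau = 0.05, chains = 2L, warmup = 2500L,
                                    draws = 1500L, gh_nodes = 8L, seed = 1L, ...) {
  bd <- x
  if (tau <= 0) stop_ctx("tau must be positive")
  gh <- make_gh_grid(gh_nodes)
  lp_fun <- function(theta) {
    ll <- bayes_loglik(theta, bd, tau, gh)
    if (!is.finite(ll)) return(-Inf)
    ll + log_prior(theta, bd$R)
  }

  # moment-based start: machine means/sd from the observed scores
  sc_true <- bd$scores[cbind(seq_len(nrow(bd$scores)), bd$z + 1L)]
  sc_false <- bd$scores[cbind(seq_len(nrow(bd$scores)), 2L - bd$z)]
  a0 <- mean(sc_true); b0 <- mean(sc_false)
  s0 <- max(stats::sd(c(sc_true - a0, sc_false - b0)), 0.05)
  cut0 <- (a0 - b0) * seq_len(bd$R - 1L) / bd$R  # offsets from b_H
  init0 <- c((a0 + b0) / 2, a0 - b0, a0, b0, log(s0), log(s0), atanh(0.1),
             cut0[1L], if (bd$R > 2L) log(pmax(diff(cut0), 1e-3)), log(0.2))

  chain_out <- vector("list", chains)
  for (ch in seq_len(chains)) {
    init <- with_seed(seed * 1000L + ch, init0 + stats::rnorm(length(init0), 0, 0.02))
    chain_out[[ch]] <- amh_chain(lp_fun, init, warmup, draws, seed + ch)
  }
  theta_draws <- do.call(rbind, lapply(chain_out, `[[`, "draws"))
  nat <- draws_natural(theta_draws, bd$R, tau)
  rhat <- split_rhat(lapply(chain_out, `[[`, "draws"))
  names(rhat) <- theta_names(bd$R)
  converged <- all(rhat <= 1.05)
  if (!converged) {
    warning("split R-hat above 1.05 for: ",
            paste(names(rhat)[rhat > 1.05], collapse = ", "),
            "; fit flagged non-converged", call. = FALSE)
  }
  structure(list(draws = nat,
                 diagnostics = list(
                   rhat = rhat,
                   accept_rate = vapply(chain_out, `[[`, numeric(1), "accept_rate"),
                   divergences = 0L,
                   converged = converged),
                 config = list(R = bd$R, tau = tau, chains = chains,
                               warmup = warmup, n_draws = draws,
                               gh_nodes = gh_nodes, seed = seed,
                               edges = bd$edges, human = bd$human,
                               machine = bd$machine)),
            class = "bayes_combiner")
}

#' @export
print.bayes_combiner <- function(x, ...) {
  cat("Bayesian combination model fit (", nrow(x$draws), " posterior draws, ",
      x$config$chains, " chains)\n", sep = "")
  cat(sprintf("  members: %s (human) + %s (machine); R = %d, tau = %g\n",
              x$config$human %||% "?", x$config$machine %||% "?",
              x$config$R, x$config$tau))
  if (!x$diagnostics$converged) cat("  [flagged non-converged]\n")
  print(round(coef(x), 4))
  invisible(x)
}

#' @export
coef.bayes_combiner <- function(object, ...) colMeans(object$draws)

#' @export
summary.bayes_combiner <- function(object, prob = 0.9, ...) {
  lo <- (1 - prob) / 2
  qs <- t(apply(object$draws, 2L, stats::quantile, probs = c(lo, 0.5, 1 - lo)))
  out <- data.frame(mean = colMeans(object$draws),
                    sd = apply(object$draws, 2L, stats::sd),
                    lower = qs[, 1L], median = qs[, 2L], upper = qs[, 3L],
                    rhat = object$diagnostics$rhat)
  structure(list(table = out, prob = prob,
                 accept_rate = object$diagnostics$accept_rate,
                 converged = object$diagnostics$converged),
            class = "summary.bayes_combiner")
}

#' @export
print.summary.bayes_combiner <- function(x, ...) {
  cat(sprintf("Posterior summary (%d%% intervals), accept rate %s, converged = %s\n",
              round(100 * x$prob),
              paste(sprintf("%.2f", x$accept_rate), collapse = "/"),
              x$converged))
  print(round(x$table, 4))
  invisible(x)
}

#' Simulate observations from the Bayesian generative model
#'
#' Draws, per item and class, correlated human/machine latent scores with
#' means `b + (a - b) * 1[z = j]`; the machine emits its latent scores
#' directly, the human choice is categorical in the temperature softmax of
#' its latent scores and the human rating is ordered-logistic in the
#' chosen-class latent score.
#'
#' @param params a [bayes_params].
#' @param truth 0-based true labels, one per item.
#' @param seed integer seed (same seed, same output).
#' @return List with `scores` (items x classes machine matrix), `y` (human
#'   choices) and `r` (human ratings).
#' @export
simulate_generative <- function(params, truth, seed = 1L) {
  stopifnot(inherits(params, "bayes_params"))
  L <- params$n_classes
  n <- length(truth)
  with_seed(seed, {
    Z1 <- matrix(stats::rnorm(n * L), n, L)
    Z2 <- matrix(stats::rnorm(n * L), n, L)
    ind <- matrix(0, n, L)
    ind[cbind(seq_len(n), truth + 1L)] <- 1
    mu_M <- params$b_M + (params$a_M - params$b_M) * ind
    mu_H <- params$b_H + (params$a_H - params$b_H) * ind
    scores <- mu_M + params$sigma_M * Z1
    lat_H <- mu_H + params$sigma_H * (params$rho * Z1 + sqrt(1 - params$rho^2) * Z2)
    p_choice <- exp((lat_H - apply(lat_H, 1L, max)) / params$tau)
    p_choice <- p_choice / rowSums(p_choice)
    y <- vapply(seq_len(n), function(i) {
      sample.int(L, 1L, prob = p_choice[i, ]) - 1L
    }, integer(1))
    chosen_lat <- lat_H[cbind(seq_len(n), y + 1L)]
    pmf <- ordered_logistic_pmf(chosen_lat, params$cutpoints, params$delta)
    pmf <- matrix(pmf, nrow = n)
    r <- vapply(seq_len(n), function(i) {
      sample.int(ncol(pmf), 1L, prob = pmf[i, ]) - 1L
    }, integer(1))
    list(scores = scores, y = y, r = r)
  })
}

# observation-level log-likelihood for a candidate truth label, one draw
predict_bayes_loglik <- function(p, scores, y, r, z_cand, gh) {
  # scores: 1 x 2; returns scalar log p(pi_M, y, r | z = z_cand, theta)
  ind <- as.numeric(c(0L, 1L) == z_cand)
  mu_M <- p$b_M + (p$a_M - p$b_M) * ind
  mu_H <- p$b_H + (p$a_H - p$b_H) * ind
  ll_m <- sum(stats::dnorm(scores, mu_M, p$sigma_M, log = TRUE))
  slope <- p$rho * p$sigma_H / p$sigma_M
  m <- mu_H + slope * (scores - mu_M)
  s <- p$sigma_H * sqrt(1 - p$rho^2)
  P0 <- m[1L] + s * gh$x0
  P1 <- m[2L] + s * gh$x1
  w0 <- stats::plogis((P0 - P1) / p$tau)
  sel <- if (y == 0L) w0 else 1 - w0
  py <- if (y == 0L) P0 else P1
  R <- length(p$cutpoints) + 1L
  if (r == 0L) {
    pmf <- stats::plogis((p$cutpoints[1L] - py) / p$delta)
  } else if (r == R - 1L) {
    pmf <- 1 - stats::plogis((p$cutpoints[R - 1L] - py) / p$delta)
  } else {
    pmf <- stats::plogis((p$cutpoints[r + 1L] - py) / p$delta) -
      stats::plogis((p$cutpoints[r] - py) / p$delta)
  }
  ll_m + log(max(sum(gh$w * sel * pmf), 1e-300))
}

#' Posterior class probabilities from a Bayesian combination fit
#'
#' For each observation `(pi_M, y_H, r_H)` and each candidate true label,
#' the likelihood of the observation is computed per posterior draw -- the
#' human latent scores marginalized by Gauss-Hermite quadrature given the
#' machine scores -- averaged over draws, and normalized across candidates
#' by Bayes' rule under a uniform label prior.
#'
#' @param object a `bayes_combiner` fit.
#' @param newdata a `bayes_data` object, or a list with `scores` (n x 2
#'   machine score matrix), `y` (choices) and `r` (ratings; continuous
#'   confidences are discretized with the training bin edges).
#' @param n_draws number of (evenly thinned) posterior draws to average
#'   over.
#' @param gh_nodes Gauss-Hermite nodes per latent dimension.
#' @param ... unused.
#' @return `n x 2` matrix of posterior label probabilities (rows sum to 1).
#' @export
predict.bayes_combiner <- function(object, newdata, n_draws = 100L,
                                   gh_nodes = 8L, ...) {
  scores <- newdata$scores
  y <- newdata$y
  r <- newdata$r
  if (inherits(newdata, "bayes_data")) {
    scores <- scores[newdata$item_of, , drop = FALSE]
  }
  if (!is.matrix(scores)) scores <- matrix(scores, ncol = 2L)
  if (!is.integer(r) && !is.null(object$config$edges)) {
    r <- as.integer(discretize_confidence(r, object$config$R,
                                          edges = object$config$edges))
  }
  gh <- make_gh_grid(gh_nodes)
  nd <- nrow(object$draws)
  take <- unique(round(seq(1L, nd, length.out = min(n_draws, nd))))
  R <- object$config$R
  tau <- object$config$tau
  params <- lapply(take, function(i) {
    d <- object$draws[i, ]
    list(a_H = d[["a_H"]], b_H = d[["b_H"]], a_M = d[["a_M"]], b_M = d[["b_M"]],
         sigma_H = d[["sigma_H"]], sigma_M = d[["sigma_M"]], rho = d[["rho"]],
         cutpoints = unname(d[paste0("c_", seq_len(R - 1L))]),
         delta = d[["delta"]], tau = tau)
  })
  n <- nrow(scores)
  out <- matrix(NA_real_, n, 2L,
                dimnames = list(NULL, c("class_0", "class_1")))
  for (i in seq_len(n)) {
    for (z in 0:1) {
      lls <- vapply(params, predict_bayes_loglik, numeric(1),
                    scores = scores[i, ], y = y[i], r = r[i], z_cand = z,
                    gh = gh)
      out[i, z + 1L] <- exp(logsumexp(lls) - log(length(lls)))
    }
    out[i, ] <- out[i, ] / sum(out[i, ])
  }
  out
}
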