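# Confidence-weighted logistic combination model.
#
# Binary panels: the model predicts the probability of the (arbitrarily
# assigned) first option, p = 1 / (1 + exp(-(b_I + sum_k b_k x_k))), where
# x_k is member k's signed confidence for class 0. Multiclass panels use
# the conditional-logit extension: evidence_j = sum_k b_k x[i, j, k] with
# member weights shared across classes and a softmax over classes; a shared
# intercept cancels there and is omitted (optional per-class intercepts are
# available). Member and extra-column weights carry a small ridge penalty
# (never the intercept) so that separable cross-validation folds still give
# finite weights.

binary_design <- function(features) {
  x0 <- class_slice(features$X, 1L)
  colnames(x0) <- features$members
  D <- cbind(`(intercept)` = 1, x0)
  if (!is.null(features$extras)) D <- cbind(D, features$extras)
  D
}

penalized_binary_loglik <- function(beta, D, y, ridge) {
  eta <- drop(D %*% beta)
  # numerically stable log(1 + exp(eta))
  lse <- ifelse(eta > 0, eta + log1p(exp(-eta)), log1p(exp(eta)))
  sum(y * eta - lse) - 0.5 * ridge * sum(beta[-1L]^2)
}

fit_logistic_binary <- function(features, y, ridge, tol, maxit, init = NULL) {
  D <- binary_design(features)
  p_dim <- ncol(D)
  pen <- c(0, rep(ridge, p_dim - 1L))
  beta <- if (is.null(init)) numeric(p_dim) else init
  ll <- penalized_binary_loglik(beta, D, y, ridge)
  converged <- FALSE
  for (it in seq_len(maxit)) {
    eta <- drop(D %*% beta)
    p <- stats::plogis(eta)
    w <- pmax(p * (1 - p), 1e-12)
    g <- drop(crossprod(D, y - p)) - pen * beta
    H <- crossprod(D * w, D)
    diag(H) <- diag(H) + pen
    step <- tryCatch(solve(H, g), error = function(e) NULL)
    if (is.null(step)) step <- g / max(diag(H))
    # damped Newton: halve until the penalized log-likelihood improves
    s <- 1
    repeat {
      beta_new <- beta + s * step
      ll_new <- penalized_binary_loglik(beta_new, D, y, ridge)
      if (is.finite(ll_new) && ll_new >= ll - 1e-12) break
      s <- s / 2
      if (s < 1e-10) { beta_new <- beta; ll_new <- ll; break }
    }
    done <- abs(ll_new - ll) <= tol * (abs(ll) + 1e-10)
    beta <- beta_new
    ll <- ll_new
    if (done) { converged <- TRUE; break }
  }
  if (!converged || any(abs(beta) > 1e6)) {
    converged <- converged && all(abs(beta) <= 1e6)
    if (!converged) {
      warning("logistic fit did not converge (possible complete separation with ",
              "ridge = ", ridge, "); weights may be at the optimizer bound",
              call. = FALSE)
    }
  }
  names(beta) <- colnames(D)
  list(beta = beta, loglik = ll, converged = converged)
}

multiclass_nll <- function(beta, X, z, ridge, class_int) {
  n <- dim(X)[1]; L <- dim(X)[2]; K <- dim(X)[3]
  b <- beta[seq_len(K)]
  evid <- matrix(0, n, L)
  for (k in seq_len(K)) evid <- evid + b[k] * X[, , k]
  if (class_int) evid <- evid + matrix(c(0, beta[-seq_len(K)]), n, L, byrow = TRUE)
  m <- apply(evid, 1L, max)
  lse <- m + log(rowSums(exp(evid - m)))
  -(sum(evid[cbind(seq_len(n), z + 1L)] - lse)) + 0.5 * ridge * sum(b^2)
}

multiclass_grad <- function(beta, X, z, ridge, class_int) {
  n <- dim(X)[1]; L <- dim(X)[2]; K <- dim(X)[3]
  b <- beta[seq_len(K)]
  evid <- matrix(0, n, L)
  for (k in seq_len(K)) evid <- evid + b[k] * X[, , k]
  if (class_int) evid <- evid + matrix(c(0, beta[-seq_len(K)]), n, L, byrow = TRUE)
  p <- exp(evid - apply(evid, 1L, max))
  p <- p / rowSums(p)
  gb <- vapply(seq_len(K), function(k) {
    -sum(X[cbind(seq_len(n), z + 1L, rep(k, n))] - rowSums(p * X[, , k]))
  }, numeric(1)) + ridge * b
  if (class_int) {
    obs <- tabulate(z + 1L, nbins = L)
    gi <- -(obs - colSums(p))[-1L]
    c(gb, gi)
  } else gb
}

#' Fit the confidence-weighted logistic combination model (low level)
#'
#' Maximizes the ridge-penalized log-likelihood of the binary logistic model
#' (for two classes) or its conditional-logit multiclass extension over a
#' prepared signed-confidence [feature_matrix]. Deterministic: no random
#' initialization, damped Newton (binary) or BFGS with analytic gradient
#' (multiclass) from zero.
#'
#' @param features a [feature_matrix] from [build_feature_matrix()].
#' @param outcomes integer vector of true labels (0-based), one per
#'   observation.
#' @param ridge non-negative ridge strength on member/extra weights (never
#'   the intercept).
#' @param per_class_intercept multiclass only: estimate per-class intercepts
#'   (class 0 fixed at 0). Default off.
#' @param tol relative log-likelihood convergence tolerance.
#' @param maxit maximum iterations.
#' @param init optional warm-start coefficient vector.
#' @return Object of class `logit_fit` with `beta_intercept`,
#'   `beta_members` (named by agent), `beta_extra`, `ridge`, `converged`,
#'   `n_train` and the attained penalized `loglik`.
#' @export
fit_logistic <- function(features, outcomes, ridge = 1e-4,
                         per_class_intercept = FALSE,
                         tol = 1e-8, maxit = 500L, init = NULL) {
  n <- dim(features$X)[1]
  if (n < 1L) stop_ctx("at least one observation is required")
  if (length(outcomes) != n) stop_ctx("outcomes length must match observations")
  if (ridge < 0) stop_ctx("ridge must be non-negative")
  L <- features$n_classes
  K <- length(features$members)
  n_extra <- if (is.null(features$extras)) 0L else ncol(features$extras)

  if (L == 2L) {
    y <- as.numeric(outcomes == 0L)
    res <- fit_logistic_binary(features, y, ridge, tol, maxit, init)
    beta <- res$beta
    fit <- list(beta_intercept = unname(beta[1L]),
                beta_members = beta[1L + seq_len(K)],
                beta_extra = if (n_extra) beta[1L + K + seq_len(n_extra)] else numeric(0),
                beta_class = NULL,
                ridge = ridge, converged = res$converged, n_train = n,
                loglik = res$loglik, n_classes = L, members = features$members,
                team = features$team)
  } else {
    if (n_extra) stop_ctx("interaction/polynomial columns require a binary panel")
    p_dim <- K + if (per_class_intercept) L - 1L else 0L
    start <- if (is.null(init)) numeric(p_dim) else init
    opt <- stats::optim(start, fn = multiclass_nll, gr = multiclass_grad,
                        X = features$X, z = outcomes, ridge = ridge,
                        class_int = per_class_intercept, method = "BFGS",
                        control = list(maxit = maxit, reltol = tol))
    beta <- opt$par
    fit <- list(beta_intercept = 0,
                beta_members = stats::setNames(beta[seq_len(K)], features$members),
                beta_extra = numeric(0),
                beta_class = if (per_class_intercept) c(0, beta[-seq_len(K)]) else NULL,
                ridge = ridge, converged = opt$convergence == 0L, n_train = n,
                loglik = -opt$value, n_classes = L, members = features$members,
                team = features$team)
    if (!fit$converged) {
      warning("conditional-logit fit did not converge", call. = FALSE)
    }
  }
  names(fit$beta_members) <- features$members
  class(fit) <- "logit_fit"
  fit
}

coef_vector <- function(fit) {
  c(`(intercept)` = fit$beta_intercept, fit$beta_members, fit$beta_extra)
}

#' Predicted class probabilities from a logistic combination fit
#'
#' @param object a `logit_fit`.
#' @param features a [feature_matrix] built for the same team (member sets
#'   must match).
#' @param type `"prob"` for an `n x L` probability matrix, `"label"` for
#'   0-based predicted labels (exact probability ties break to the lowest
#'   class index; an attribute `tie_count` reports how many).
#' @param ... unused.
#' @export
predict.logit_fit <- function(object, features, type = c("prob", "label"), ...) {
  type <- match.arg(type)
  if (!identical(features$members, object$members)) {
    stop_ctx("feature members do not match the fitted team: expected ",
             paste(object$members, collapse = ", "))
  }
  L <- object$n_classes
  n <- dim(features$X)[1]
  if (L == 2L) {
    D <- binary_design(features)
    eta <- drop(D %*% coef_vector(object))
    p0 <- stats::plogis(eta)
    prob <- cbind(p0, 1 - p0)
  } else {
    evid <- matrix(0, n, L)
    for (k in seq_along(object$members)) {
      evid <- evid + object$beta_members[k] * features$X[, , k]
    }
    if (!is.null(object$beta_class)) {
      evid <- evid + matrix(object$beta_class, n, L, byrow = TRUE)
    }
    prob <- exp(evid - apply(evid, 1L, max))
    prob <- prob / rowSums(prob)
  }
  colnames(prob) <- paste0("class_", seq_len(L) - 1L)
  if (type == "prob") return(prob)
  lab <- max.col(prob, ties.method = "first") - 1L
  ties <- apply(prob, 1L, function(p) sum(p == max(p)) > 1L)
  attr(lab, "tie_count") <- sum(ties)
  lab
}

#' Fit a confidence-weighted logistic combiner to a panel
#'
#' High-level interface: pairs the team members' records into observations,
#' builds the signed-confidence features and fits the logistic combination
#' model. Returns a classed model object with the usual `print`, `summary`,
#' `coef` and `predict` methods.
#'
#' @param panel a [judgment_panel].
#' @param team a [team_spec] (or character vector of member agent ids).
#' @inheritParams fit_logistic
#' @param observations optional pre-computed pairing.
#' @return Object of class `c("logit_combiner", "logit_fit")`.
#' @examples
#' panel <- simulate_panel(panel_spec(
#'   n_items = 60, n_classes = 2,
#'   agents = list(
#'     agent_spec("rater", "human_discrete", target_accuracy = 0.7),
#'     agent_spec("model", "machine_perplexity", target_accuracy = 0.72)),
#'   seed = 7))
#' fit <- logit_combiner(panel, c("rater", "model"))
#' coef(fit)
#' @export
logit_combiner <- function(panel, team, ridge = 1e-4,
                           per_class_intercept = FALSE, observations = NULL, ...) {
  team <- as_team_spec(team)
  fm <- build_feature_matrix(panel, team, observations)
  fit <- fit_logistic(fm, feature_outcomes(panel, fm), ridge = ridge,
                      per_class_intercept = per_class_intercept, ...)
  fit$panel_info <- list(n_items = panel$n_items, n_classes = panel$n_classes)
  class(fit) <- c("logit_combiner", "logit_fit")
  fit
}

#' @export
print.logit_fit <- function(x, ...) {
  cat("Confidence-weighted logistic combination model\n")
  cat(sprintf("  %d classes, %d members, n = %d, ridge = %g%s\n",
              x$n_classes, length(x$members), x$n_train, x$ridge,
              if (!x$converged) " [NOT CONVERGED]" else ""))
  print(round(coef_vector(x), 4))
  invisible(x)
}

#' @export
coef.logit_fit <- function(object, ...) coef_vector(object)

#' @export
summary.logit_fit <- function(object, ...) {
  structure(list(coef = coef_vector(object), n = object$n_train,
                 loglik = object$loglik, converged = object$converged,
                 ridge = object$ridge, members = object$members),
            class = "summary.logit_fit")
}

#' @export
print.summary.logit_fit <- function(x, ...) {
  cat("Logistic combination fit over", length(x$members), "member(s):",
      paste(x$members, collapse = ", "), "\n")
  cat(sprintf("  n = %d, penalized log-likelihood = %.4f, converged = %s\n",
              x$n, x$loglik, x$converged))
  print(round(x$coef, 4))
  invisible(x)
}

#' Select per-member calibration-squashing strengths on a grid
#'
#' For each member in turn, evaluates grouped leave-one-out accuracy on the
#' supplied (training) panel for every `alpha` in the grid and keeps the
#' maximizer; accuracy ties resolve to the smaller `alpha` (the simpler
#' model). A member whose confidence is informative keeps `alpha = 0`
#' (identity); a member whose confidence is pure noise is pushed to the top
#' of the grid, where the transform flattens every magnitude to 1.
#'
#' @param panel a [judgment_panel] (training data only: the held-out item of
#'   any outer evaluation loop must not be in here).
#' @param team a [team_spec] or member ids.
#' @param alpha_grid non-empty grid of non-negative values; must include 0.
#' @param members members to tune (default: all in the team).
#' @param ridge ridge strength passed through to the fits.
#' @return Named numeric vector of selected `alpha` values (tuned members
#'   only), with attribute `"accuracy"` holding each member's grid of inner
#'   LOOCV accuracies.
#' @export
fit_alpha <- function(panel, team, alpha_grid = c(0, 1, 16),
                      members = NULL, ridge = 1e-4) {
  team <- as_team_spec(team)
  if (!length(alpha_grid) || !0 %in% alpha_grid) {
    stop_ctx("`alpha_grid` must be non-empty and include 0")
  }
  alpha_grid <- sort(unique(alpha_grid))
  if (is.null(members)) members <- team$members
  chosen <- stats::setNames(rep(0, length(members)), members)
  acc_grid <- list()
  current <- stats::setNames(rep(0, length(team$members)), team$members)
  for (m in members) {
    accs <- vapply(alpha_grid, function(a) {
      al <- current
      al[m] <- a
      tm <- team
      tm$alpha <- al
      loocv(panel, tm, ridge = ridge)$accuracy
    }, numeric(1))
    best <- alpha_grid[which.max(accs)]  # which.max takes the first (smallest) tie
    chosen[m] <- best
    current[m] <- best
    acc_grid[[m]] <- stats::setNames(accs, alpha_grid)
  }
  attr(chosen, "accuracy") <- acc_grid
  chosen
}
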