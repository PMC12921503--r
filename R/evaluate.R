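# Team evaluation: grouped leave-one-out cross-validation, shuffle
# controls, accuracy comparisons, and the calibration/diversity
# diagnostics that underpin complementarity.

make_team_eval <- function(team, predictions, tie_count = 0L, seed = NA_integer_,
                           extra = list()) {
  n <- nrow(predictions)
  acc <- if (n) mean(predictions$correct) else NA_real_
  structure(c(list(team = team, predictions = predictions,
                   accuracy = acc,
                   sem = if (n) sqrt(acc * (1 - acc) / n) else NA_real_,
                   n_evaluations = n, tie_count = tie_count, seed = seed),
              extra),
            class = "team_eval")
}

#' @export
print.team_eval <- function(x, ...) {
  cat(sprintf("Team [%s] (%s): accuracy %.4f +/- %.4f SEM over %d evaluations",
              paste(x$team$members, collapse = " + "), x$team$combiner,
              x$accuracy, x$sem, x$n_evaluations))
  if (x$tie_count > 0) cat(sprintf(" (%d prediction ties)", x$tie_count))
  cat("\n")
  invisible(x)
}

predict_labels_majority <- function(panel, fm) {
  n <- dim(fm$X)[1]
  L <- fm$n_classes
  votes <- matrix(0L, n, L)
  for (m in fm$members) {
    ch <- panel$records$chosen_label[fm$observations[[paste0("rec.", m)]]]
    votes[cbind(seq_len(n), ch + 1L)] <- votes[cbind(seq_len(n), ch + 1L)] + 1L
  }
  lab <- max.col(votes, ties.method = "first") - 1L
  ties <- apply(votes, 1L, function(v) sum(v == max(v)) > 1L)
  attr(lab, "tie_count") <- sum(ties)
  lab
}

#' Grouped leave-one-out cross-validation of a team
#'
#' For every test item, all observations of that item are held out, the
#' team's combiner is trained on all observations of the remaining items,
#' and the held-out observations are predicted; the pooled predictions give
#' the team accuracy with its binomial standard error
#' `sqrt(p (1 - p) / n)`. Single-member teams skip training: the member's
#' own recorded choices are scored directly. Items lacking a record for
#' some team member are excluded with a warning. A leakage guard asserts,
#' on every fold, that the held-out item never contributes training rows.
#'
#' @param panel a [judgment_panel].
#' @param team a [team_spec] or character vector of member ids (then
#'   combined with the logistic combiner).
#' @param ridge ridge strength for the logistic combiner.
#' @param n_folds optional number of grouped folds; default `NULL` means
#'   true leave-one-item-out. Smaller values give grouped k-fold CV (items
#'   are split into contiguous blocks), mainly useful to keep the Bayesian
#'   combiner affordable.
#' @param keep_folds record the train/test item composition of every fold
#'   (attribute `"folds"`) for auditing.
#' @param ... further arguments passed to the combiner
#'   ([fit_logistic()] or [fit_bayesian()]).
#' @return A `team_eval` object: per-observation predictions with
#'   correctness flags, `accuracy`, binomial `sem`, `n_evaluations` and
#'   `tie_count`.
#' @export
loocv <- function(panel, team, ridge = 1e-4, n_folds = NULL,
                  keep_folds = FALSE, ...) {
  team <- as_team_spec(team)
  obs <- pair_observations(panel, team$members, on_missing = "drop")
  fm <- build_feature_matrix(panel, team, obs)
  y <- feature_outcomes(panel, fm)
  items <- fm$items
  n <- length(items)
  tie_count <- 0L
  folds_audit <- list()

  if (length(team$members) == 1L) {
    # individual teammates: evaluation is the testing phase only
    pred <- panel$records$chosen_label[obs[[paste0("rec.", team$members)]]]
  } else if (team$combiner == "majority") {
    pred <- predict_labels_majority(panel, fm)
    tie_count <- attr(pred, "tie_count")
  } else {
    uitems <- unique(items)
    fold_of <- if (is.null(n_folds) || n_folds >= length(uitems)) {
      stats::setNames(seq_along(uitems), uitems)
    } else {
      stats::setNames(cut(seq_along(uitems), n_folds, labels = FALSE), uitems)
    }
    obs_fold <- fold_of[items]
    pred <- integer(n)
    if (team$combiner == "logistic") {
      warm <- fit_logistic(fm, y, ridge = ridge, ...)
      warm_par <- c(coef_vector(warm), warm$beta_class[-1L])
      if (fm$n_classes > 2L) {
        warm_par <- c(unname(warm$beta_members), warm$beta_class[-1L])
      }
      for (f in unique(obs_fold)) {
        test <- which(obs_fold == f)
        train <- which(obs_fold != f)
        held <- unique(items[test])
        stopifnot(!any(items[train] %in% held))  # leakage guard
        fit <- fit_logistic(subset_features(fm, train), y[train],
                            ridge = ridge, init = warm_par, ...)
        lab <- predict(fit, subset_features(fm, test), type = "label")
        pred[test] <- lab
        tie_count <- tie_count + attr(lab, "tie_count")
        if (keep_folds) {
          folds_audit[[length(folds_audit) + 1L]] <-
            list(held = held, train_items = unique(items[train]))
        }
      }
    } else if (team$combiner == "bayesian") {
      bd <- bayes_data_from_panel(panel, team, obs)
      for (f in unique(obs_fold)) {
        test <- which(obs_fold == f)
        train <- which(obs_fold != f)
        held <- unique(items[test])
        stopifnot(!any(items[train] %in% held))  # leakage guard
        fit <- fit_bayesian(subset_bayes_data(bd, train), ...)
        prob <- predict(fit, subset_bayes_data(bd, test))
        lab <- max.col(prob, ties.method = "first") - 1L
        tie_count <- tie_count + sum(apply(prob, 1L, function(p) sum(p == max(p)) > 1L))
        pred[test] <- lab
        if (keep_folds) {
          folds_audit[[length(folds_audit) + 1L]] <-
            list(held = held, train_items = unique(items[train]))
        }
      }
    } else {
      stop_ctx("unsupported combiner: ", team$combiner)
    }
  }

  predictions <- data.frame(item_id = items, predicted = as.integer(pred),
                            true_label = y, correct = as.integer(pred == y))
  out <- make_team_eval(team, predictions, tie_count = tie_count)
  if (keep_folds) attr(out, "folds") <- folds_audit
  out
}

#' Enumerate all non-empty team subsets of a set of agents
#'
#' @param agents character vector of agent ids, or an agents data.frame
#'   (with `agent_id` and `agent_type`; teams are then tagged
#'   `with_human`).
#' @param combiner combiner assigned to every team.
#' @param ... further [team_spec()] options applied to every team.
#' @return List of `team_spec` objects (`2^K - 1` of them), each carrying a
#'   logical attribute `with_human` when agent types are known.
#' @export
enumerate_teams <- function(agents, combiner = "logistic", ...) {
  if (is.data.frame(agents)) {
    ids <- as.character(agents$agent_id)
    human <- startsWith(as.character(agents$agent_type), "human")
    names(human) <- ids
  } else {
    ids <- as.character(agents)
    human <- NULL
  }
  if (!length(ids)) stop_ctx("at least one agent is required")
  teams <- list()
  for (size in seq_along(ids)) {
    sets <- utils::combn(ids, size, simplify = FALSE)
    for (s in sets) {
      tm <- team_spec(s, combiner = combiner, ...)
      if (!is.null(human)) attr(tm, "with_human") <- any(human[s])
      teams[[length(teams) + 1L]] <- tm
    }
  }
  teams
}

#' Shuffle control: score randomly permuted predictions
#'
#' Permutes the predicted labels of a team evaluation across observations
#' (seeded) and rescores them against the truth. Expected accuracy is the
#' chance level `1/L`; a pipeline whose shuffled accuracy stays above
#' chance leaks information.
#'
#' @param panel a [judgment_panel].
#' @param team a [team_spec] or member ids.
#' @param seed integer seed for the permutation.
#' @param result optional existing `team_eval` for this team (recomputed
#'   via [loocv()] when `NULL`).
#' @param ... passed to [loocv()] when `result` is `NULL`.
#' @return A `team_eval` of the shuffled predictions (metadata flag
#'   `shuffled = TRUE`).
#' @export
shuffle_control <- function(panel, team, seed, result = NULL, ...) {
  if (is.null(result)) result <- loocv(panel, team, ...)
  pred <- result$predictions
  perm <- with_seed(seed, sample.int(nrow(pred)))
  pred$predicted <- pred$predicted[perm]
  pred$correct <- as.integer(pred$predicted == pred$true_label)
  make_team_eval(result$team, pred, tie_count = result$tie_count, seed = seed,
                 extra = list(shuffled = TRUE))
}

acc_values <- function(x) {
  if (is.numeric(x)) return(as.numeric(x))
  if (inherits(x, "team_eval")) return(x$accuracy)
  vapply(x, function(e) if (inherits(e, "team_eval")) e$accuracy else as.numeric(e),
         numeric(1))
}

#' Compare two groups of team accuracies
#'
#' Welch's two-sample t test (Welch--Satterthwaite degrees of freedom) for
#' unpaired groups, or a one-sample t test on the differences for paired
#' lists. Groups are lists of `team_eval` objects (one accuracy per team)
#' or plain numeric vectors.
#'
#' @param a,b groups to compare.
#' @param paired treat `a` and `b` as paired (equal length)?
#' @param alternative `"two.sided"` (default), `"less"` or `"greater"`.
#' @return List with `statistic`, `df`, `p.value` and `method`.
#' @export
compare_accuracies <- function(a, b, paired = FALSE,
                               alternative = c("two.sided", "less", "greater")) {
  alternative <- match.arg(alternative)
  x <- acc_values(a)
  y <- acc_values(b)
  if (length(x) < 2L || length(y) < 2L) stop_ctx("need at least two results per group")
  if (stats::var(x) == 0 && stats::var(y) == 0) {
    stop_ctx("undefined statistic: zero variance in both groups")
  }
  tt <- stats::t.test(x, y, paired = paired, var.equal = FALSE,
                      alternative = alternative)
  list(statistic = unname(tt$statistic), df = unname(tt$parameter),
       p.value = tt$p.value, method = tt$method)
}

#' Confidence-accuracy calibration curve for one agent
#'
#' Sorts the agent's observations by confidence into equal-count bins
#' (remainder spread over the lowest bins) and reports each bin's mean
#' confidence, mean accuracy and count, plus the least-squares slope of bin
#' accuracy on bin index (and, for reference, on bin mean confidence). A
#' positive slope is the calibration condition for complementarity: higher
#' confidence goes with higher accuracy.
#'
#' @param panel a [judgment_panel].
#' @param agent_id agent to diagnose.
#' @param n_bins number of equal-count bins (reduced with a warning when
#'   the agent has fewer observations).
#' @return Object of class `calibration_curve`: `bins` data.frame, `slope`
#'   (on bin index), `slope_confidence` (on bin mean confidence),
#'   `degenerate` flag (constant confidence: slope reported as 0).
#' @export
calibration_curve <- function(panel, agent_id, n_bins = 5L) {
  idx <- which(panel$records$agent_id == agent_id)
  if (!length(idx)) stop_ctx("no records for agent ", agent_id)
  rec <- panel$records[idx, , drop = FALSE]
  conf <- rec$confidence
  correct <- as.integer(rec$chosen_label == unname(panel$truth[rec$item_id]))
  m <- length(conf)
  if (m < n_bins) {
    warning("agent ", agent_id, " has only ", m, " observations; using ",
            m, " bins", call. = FALSE)
    n_bins <- m
  }
  degenerate <- length(unique(conf)) == 1L
  if (degenerate) n_bins <- 1L
  ord <- order(conf)
  sizes <- rep(m %/% n_bins, n_bins)
  r <- m %% n_bins
  if (r > 0) sizes[seq_len(r)] <- sizes[seq_len(r)] + 1L
  bin <- rep(seq_len(n_bins), times = sizes)
  bins <- data.frame(
    bin = seq_len(n_bins),
    mean_confidence = as.numeric(tapply(conf[ord], bin, mean)),
    mean_accuracy = as.numeric(tapply(correct[ord], bin, mean)),
    count = as.integer(sizes)
  )
  if (n_bins >= 2L) {
    slope <- unname(stats::coef(stats::lm(mean_accuracy ~ bin, data = bins))[2L])
    slope_conf <- if (length(unique(bins$mean_confidence)) > 1L) {
      unname(stats::coef(stats::lm(mean_accuracy ~ mean_confidence, data = bins))[2L])
    } else 0
  } else {
    slope <- 0
    slope_conf <- 0
  }
  structure(list(agent_id = agent_id, bins = bins, slope = slope,
                 slope_confidence = slope_conf, degenerate = degenerate),
            class = "calibration_curve")
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat("Calibration curve for", x$agent_id,
      sprintf("(slope on bin index: %.4f%s)\n", x$slope,
              if (x$degenerate) ", degenerate: constant confidence" else ""))
  print(x$bins, row.names = FALSE)
  invisible(x)
}

#' @export
plot.calibration_curve <- function(x, ...) {
  graphics::plot(x$bins$bin, x$bins$mean_accuracy, type = "b",
                 xlab = "confidence bin", ylab = "accuracy",
                 main = paste("Calibration:", x$agent_id), ...)
  graphics::abline(stats::lm(mean_accuracy ~ bin, data = x$bins), lty = 2)
  invisible(x)
}

#' Per-item difficulty profile of one agent
#'
#' Larger values mean easier items for every agent type: perplexity agents
#' use `q(incorrect) - q(correct)` (binary panels; how much worse the wrong
#' version looks), probability-score agents use the score at the true
#' label, and humans use their mean per-item correctness.
#'
#' @param panel a [judgment_panel].
#' @param agent_id agent to profile.
#' @return Named numeric vector over the items the agent judged.
#' @export
item_difficulty <- function(panel, agent_id) {
  type <- agent_type_of(panel, agent_id)
  idx <- which(panel$records$agent_id == agent_id)
  if (!length(idx)) stop_ctx("no records for agent ", agent_id)
  rec <- panel$records[idx, , drop = FALSE]
  truth <- unname(panel$truth[rec$item_id])
  val <- if (type == "machine_perplexity") {
    if (panel$n_classes != 2L) {
      stop_ctx("perplexity difficulty is defined for binary panels")
    }
    pc <- ppl_cols(panel)
    if (is.null(pc)) stop_ctx("panel has no perplexity columns")
    Q <- as.matrix(rec[, pc, drop = FALSE])
    Q[cbind(seq_len(nrow(Q)), 2L - truth)] - Q[cbind(seq_len(nrow(Q)), truth + 1L)]
  } else if (type == "machine_scores") {
    sc <- score_cols(panel)
    if (is.null(sc)) stop_ctx("panel has no score columns")
    S <- as.matrix(rec[, sc, drop = FALSE])
    S[cbind(seq_len(nrow(S)), truth + 1L)]
  } else {
    as.numeric(rec$chosen_label == truth)
  }
  out <- tapply(val, rec$item_id, mean)
  stats::setNames(as.numeric(out), names(out))
}

#' Pairwise item-difficulty diversity matrix
#'
#' Spearman rank correlations of per-item difficulty between every pair of
#' agents, over the items both judged (ties mid-ranked). Low correlations
#' mean the agents err on different items -- the diversity condition for
#' complementarity. Pairs sharing fewer than 3 items are `NA`.
#'
#' @param panel a [judgment_panel].
#' @param agents agent ids (default: all).
#' @return Symmetric correlation matrix with unit diagonal, class
#'   `diversity_matrix`.
#' @export
diversity_matrix <- function(panel, agents = NULL) {
  if (is.null(agents)) agents <- panel$agents$agent_id
  if (length(agents) < 2L) stop_ctx("need at least two agents")
  diffs <- lapply(agents, function(a) item_difficulty(panel, a))
  names(diffs) <- agents
  K <- length(agents)
  M <- diag(1, K)
  dimnames(M) <- list(agents, agents)
  for (i in seq_len(K - 1L)) for (j in (i + 1L):K) {
    shared <- intersect(names(diffs[[i]]), names(diffs[[j]]))
    M[i, j] <- M[j, i] <- if (length(shared) < 3L) NA_real_ else {
      stats::cor(diffs[[i]][shared], diffs[[j]][shared], method = "spearman")
    }
  }
  structure(M, class = c("diversity_matrix", "matrix"))
}

#' @export
print.diversity_matrix <- function(x, ...) {
  cat("Item-difficulty Spearman correlations:\n")
  print(round(unclass(x), 3))
  invisible(x)
}

#' Write an evaluation result to disk
#'
#' Emits `<stem>.json` (team, accuracy, SEM, counts; full numeric
#' precision) and `<stem>.csv` (per-observation predictions). The pair
#' round-trips through [read_results()] exactly.
#'
#' @param result a `team_eval`.
#' @param stem output path stem (without extension).
#' @return Invisibly, the two file paths.
#' @export
write_results <- function(result, stem) {
  if (!inherits(result, "team_eval")) stop_ctx("`result` must be a team_eval")
  json_path <- paste0(stem, ".json")
  csv_path <- paste0(stem, ".csv")
  summary <- list(
    team = list(members = result$team$members, combiner = result$team$combiner,
                use_confidence = result$team$use_confidence),
    accuracy = result$accuracy, sem = result$sem,
    n_evaluations = result$n_evaluations, tie_count = result$tie_count,
    seed = result$seed
  )
  jsonlite::write_json(summary, json_path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  utils::write.csv(result$predictions, csv_path, row.names = FALSE, quote = FALSE)
  invisible(c(json_path, csv_path))
}

#' Read an evaluation result written by [write_results()]
#'
#' @param stem the path stem used when writing.
#' @return A `team_eval`.
#' @export
read_results <- function(stem) {
  s <- jsonlite::read_json(paste0(stem, ".json"), simplifyVector = TRUE)
  pred <- utils::read.csv(paste0(stem, ".csv"), stringsAsFactors = FALSE)
  pred$item_id <- as.character(pred$item_id)
  team <- team_spec(s$team$members, combiner = s$team$combiner,
                    use_confidence = s$team$use_confidence)
  out <- make_team_eval(team, pred, tie_count = s$tie_count,
                        seed = if (is.null(s$seed)) NA_integer_ else s$seed)
  stopifnot(isTRUE(all.equal(out$accuracy, s$accuracy)) || out$n_evaluations == 0L)
  out
}
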