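# Synthetic judgment panels.
#
# One shared item-difficulty factor d_i ~ N(0, 1) drives diversity: each
# agent loads on it with weight lambda (loading 1 = fully shared
# difficulty, 0 = idiosyncratic). Per observation the agent's latent
# evidence is e = s - (lambda * d_i + sqrt(1 - lambda^2) * eps), the
# judgment is correct with probability logistic(e), and the reported
# confidence mixes |e| (informative) with independent noise according to
# calibration_quality. The skill s is calibrated by root-finding so the
# expected accuracy matches the target.

#' Specify a synthetic agent
#'
#' @param agent_id identifier.
#' @param agent_type one of `"human_discrete"`, `"human_continuous"`,
#'   `"machine_scores"`, `"machine_perplexity"`.
#' @param target_accuracy expected accuracy, strictly between chance `1/L`
#'   and 1.
#' @param calibration_quality in `[0, 1]`: 1 means confidence is fully
#'   informative (|latent evidence|), 0 means confidence is independent
#'   noise.
#' @param shared_difficulty_loading in `[0, 1]`: weight on the panel-common
#'   item-difficulty factor; high loadings make agents err on the same
#'   items (low diversity).
#' @param rating_levels rating levels for `human_discrete` agents.
#' @return Object of class `agent_spec`.
#' @export
agent_spec <- function(agent_id, agent_type, target_accuracy,
                       calibration_quality = 1, shared_difficulty_loading = 0.5,
                       rating_levels = 3L) {
  if (!agent_type %in% valid_agent_types) {
    stop_ctx("unknown agent_type: ", agent_type)
  }
  if (calibration_quality < 0 || calibration_quality > 1) {
    stop_ctx("calibration_quality must lie in [0, 1]")
  }
  if (shared_difficulty_loading < 0 || shared_difficulty_loading > 1) {
    stop_ctx("shared_difficulty_loading must lie in [0, 1]")
  }
  structure(list(agent_id = as.character(agent_id), agent_type = agent_type,
                 target_accuracy = target_accuracy,
                 calibration_quality = calibration_quality,
                 shared_difficulty_loading = shared_difficulty_loading,
                 rating_levels = as.integer(rating_levels)),
            class = "agent_spec")
}

#' Specify a synthetic judgment panel
#'
#' @param n_items number of items `N >= 2`.
#' @param n_classes number of classes `L >= 2`.
#' @param agents list of [agent_spec()] objects.
#' @param humans_per_item length-2 integer range: how many observations
#'   each human-type agent contributes per item (machines always contribute
#'   one).
#' @param seed integer seed.
#' @return Object of class `panel_spec`.
#' @export
panel_spec <- function(n_items, n_classes = 2L, agents,
                       humans_per_item = c(1L, 1L), seed = 1L) {
  n_items <- as.integer(n_items)
  n_classes <- as.integer(n_classes)
  if (n_items < 2L) stop_ctx("n_items must be >= 2")
  if (n_classes < 2L) stop_ctx("n_classes must be >= 2")
  if (inherits(agents, "agent_spec")) agents <- list(agents)
  for (a in agents) {
    if (!inherits(a, "agent_spec")) stop_ctx("`agents` must be agent_spec objects")
    if (a$target_accuracy <= 1 / n_classes || a$target_accuracy >= 1) {
      stop_ctx("agent ", a$agent_id, ": target_accuracy must lie strictly ",
               "between chance (", signif(1 / n_classes, 3), ") and 1")
    }
    if (a$agent_type == "machine_perplexity" && n_classes != 2L) {
      stop_ctx("machine_perplexity agents require a binary panel")
    }
  }
  if (length(humans_per_item) == 1L) humans_per_item <- rep(humans_per_item, 2L)
  structure(list(n_items = n_items, n_classes = n_classes, agents = agents,
                 humans_per_item = as.integer(humans_per_item),
                 seed = as.integer(seed)),
            class = "panel_spec")
}

# skill s such that E[plogis(s - Z)] = target, Z ~ N(0, 1)
calibrate_skill <- function(target, gh = gh_normal(40L)) {
  acc <- function(s) sum(gh$w * stats::plogis(s - gh$x)) - target
  stats::uniroot(acc, c(-20, 20), tol = 1e-10)$root
}

#' Simulate a judgment panel
#'
#' Generates ground truth uniformly over classes and, per agent and item,
#' judgments from the shared-difficulty latent-evidence model (see the
#' package vignette). Realized accuracy matches `target_accuracy` in
#' expectation; confidence calibration and inter-agent diversity are
#' controlled per agent. Confidences are formatted per agent type: discrete
#' humans report within-agent quantile ratings `0..R-1`, continuous humans
#' report the raw confidence, perplexity agents report a perplexity pair
#' with `|delta PPL|` equal to the confidence and the lower perplexity at
#' the chosen label, and score agents report a softmax score vector whose
#' maximum increases with confidence.
#'
#' @param spec a [panel_spec()].
#' @return A validated [judgment_panel]; byte-identical for equal seeds.
#' @export
simulate_panel <- function(spec) {
  stopifnot(inherits(spec, "panel_spec"))
  L <- spec$n_classes
  N <- spec$n_items
  item_ids <- sprintf("item_%03d", seq_len(N))
  with_seed(spec$seed, {
    truth <- sample.int(L, N, replace = TRUE) - 1L
    d <- stats::rnorm(N)
    rec_list <- list()
    for (a in spec$agents) {
      s <- calibrate_skill(a$target_accuracy)
      lam <- a$shared_difficulty_loading
      cq <- a$calibration_quality
      n_per <- if (startsWith(a$agent_type, "human")) {
        sample(spec$humans_per_item[1]:spec$humans_per_item[2], N, replace = TRUE)
      } else {
        rep(1L, N)
      }
      item_rep <- rep(seq_len(N), times = n_per)
      M <- length(item_rep)
      eps <- stats::rnorm(M)
      e <- s - (lam * d[item_rep] + sqrt(1 - lam^2) * eps)
      correct <- stats::runif(M) < stats::plogis(e)
      chosen <- truth[item_rep]
      if (any(!correct)) {
        wrong <- which(!correct)
        shift <- sample.int(L - 1L, length(wrong), replace = TRUE)
        chosen[wrong] <- (truth[item_rep[wrong]] + shift) %% L
      }
      conf <- cq * abs(e) + (1 - cq) * abs(stats::rnorm(M))
      rec <- data.frame(item_id = item_ids[item_rep], agent_id = a$agent_id,
                        chosen_label = chosen, confidence = conf,
                        stringsAsFactors = FALSE)
      if (a$agent_type == "human_discrete") {
        edges <- unique(stats::quantile(conf, probs = seq_len(a$rating_levels - 1L) /
                                          a$rating_levels, names = FALSE))
        rec$confidence <- as.numeric(findInterval(conf, edges, left.open = TRUE))
      } else if (a$agent_type == "machine_perplexity") {
        conf_eps <- pmax(conf, 1e-9)
        q <- matrix(10, M, 2L)
        q[cbind(seq_len(M), 2L - chosen)] <- 10 + conf_eps  # non-chosen class
        rec$confidence <- conf_eps
        rec$ppl_0 <- q[, 1L]
        rec$ppl_1 <- q[, 2L]
      } else if (a$agent_type == "machine_scores") {
        conf_eps <- pmax(conf, 1e-9)
        logits <- matrix(0, M, L)
        logits[cbind(seq_len(M), chosen + 1L)] <- conf_eps
        sc <- exp(logits)
        sc <- sc / rowSums(sc)
        rec$confidence <- conf_eps
        for (j in seq_len(L)) rec[[paste0("score_", j - 1L)]] <- sc[, j]
      }
      rec_list[[a$agent_id]] <- rec
    }
    records <- do.call(rbind, lapply(rec_list, function(r) {
      # align optional columns across agents
      for (col in c(paste0("score_", seq_len(L) - 1L), "ppl_0", "ppl_1")) {
        if (!col %in% names(r)) r[[col]] <- NA_real_
      }
      r
    }))
    rownames(records) <- NULL
    has_scores <- any(!is.na(records[[paste0("score_", 0L)]]))
    has_ppl <- any(!is.na(records[["ppl_0"]]))
    if (!has_scores) records <- records[, !grepl("^score_", names(records))]
    if (!has_ppl) records <- records[, !grepl("^ppl_", names(records))]

    agents_df <- data.frame(
      agent_id = vapply(spec$agents, `[[`, character(1), "agent_id"),
      agent_type = vapply(spec$agents, `[[`, character(1), "agent_type"),
      rating_levels = vapply(spec$agents, function(a) {
        if (a$agent_type == "human_discrete") a$rating_levels else NA_integer_
      }, integer(1)),
      stringsAsFactors = FALSE
    )
    judgment_panel(records, stats::setNames(truth, item_ids), agents_df, L,
                   metadata = list(generator = "simulate_panel", seed = spec$seed))
  })
}

#' Generate a neuroscience-forecasting-style benchmark panel
#'
#' A binary forced-choice panel shaped like a forecasting benchmark with a
#' pooled human expert population and three language-model judges: 100
#' items; three perplexity agents with accuracies near 0.70/0.72/0.75 and
#' shared-difficulty loading 0.8 (so the machines err on similar items);
#' one pooled continuous-confidence human agent with accuracy near 0.65,
#' loading 0.3 (diverse from the machines) and 2--9 observations per item.
#' Confidence is fully informative for every agent, so both
#' complementarity conditions -- calibration and diversity -- hold by
#' construction.
#'
#' @param seed integer seed.
#' @return A validated [judgment_panel].
#' @export
make_brainbench_like <- function(seed = 1L) {
  spec <- panel_spec(
    n_items = 100L, n_classes = 2L,
    agents = list(
      agent_spec("llm_small", "machine_perplexity", target_accuracy = 0.70,
                 calibration_quality = 1, shared_difficulty_loading = 0.8),
      agent_spec("llm_mid", "machine_perplexity", target_accuracy = 0.72,
                 calibration_quality = 1, shared_difficulty_loading = 0.8),
      agent_spec("llm_large", "machine_perplexity", target_accuracy = 0.75,
                 calibration_quality = 1, shared_difficulty_loading = 0.8),
      agent_spec("human", "human_continuous", target_accuracy = 0.65,
                 calibration_quality = 1, shared_difficulty_loading = 0.3)
    ),
    humans_per_item = c(2L, 9L), seed = seed
  )
  panel <- simulate_panel(spec)
  panel$metadata$source <- "make_brainbench_like"
  panel
}

#' Destroy one agent's confidence calibration
#'
#' Permutes the named agent's confidences across its records (choices
#' untouched): accuracy and the confidence marginal are preserved while the
#' association between confidence and correctness is destroyed. Derived
#' columns (perplexity pairs, score vectors) are rebuilt to stay consistent
#' with the permuted confidences.
#'
#' @param panel a [judgment_panel].
#' @param agent_id agent whose confidence to permute.
#' @param seed integer seed.
#' @return A new [judgment_panel].
#' @export
degrade_confidence <- function(panel, agent_id, seed = 1L) {
  idx <- which(panel$records$agent_id == agent_id)
  if (!length(idx)) stop_ctx("unknown agent or no records: ", agent_id)
  type <- agent_type_of(panel, agent_id)
  rec <- panel$records
  perm <- with_seed(seed, sample(length(idx)))
  conf <- rec$confidence[idx][perm]
  rec$confidence[idx] <- conf
  if (type == "machine_perplexity") {
    chosen <- rec$chosen_label[idx]
    conf_eps <- pmax(conf, 1e-9)
    rec$ppl_0[idx] <- ifelse(chosen == 0L, 10, 10 + conf_eps)
    rec$ppl_1[idx] <- ifelse(chosen == 1L, 10, 10 + conf_eps)
    rec$confidence[idx] <- conf_eps
  } else if (type == "machine_scores") {
    L <- panel$n_classes
    chosen <- rec$chosen_label[idx]
    conf_eps <- pmax(conf, 1e-9)
    logits <- matrix(0, length(idx), L)
    logits[cbind(seq_along(idx), chosen + 1L)] <- conf_eps
    sc <- exp(logits)
    sc <- sc / rowSums(sc)
    for (j in seq_len(L)) rec[[paste0("score_", j - 1L)]][idx] <- sc[, j]
    rec$confidence[idx] <- conf_eps
  }
  judgment_panel(rec, panel$truth, panel$agents, panel$n_classes,
                 metadata = c(panel$metadata,
                              list(degraded_agent = agent_id,
                                   degrade_seed = seed)))
}
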