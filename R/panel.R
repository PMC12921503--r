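#' Judgment panels
#'
#' A judgment panel holds everything needed to evaluate human--machine teams
#' on a forced-choice task: ground-truth labels for `N` items with `L`
#' possible classes, a roster of agents (human or machine), and one record
#' per agent-by-item observation. Labels are 0-based integers `0..L-1`
#' internally; a record stores the agent's chosen label and a non-negative
#' confidence (a discrete rating for humans on an ordinal scale, a slider
#' value for continuous raters, or an absolute perplexity difference for
#' language models), plus optionally a per-class probability-score vector
#' (columns `score_0..score_{L-1}`) or a per-class perplexity vector
#' (`ppl_0..ppl_{L-1}`).
#'
#' Confidence is stored raw: discrete levels as `0..R-1` integers cast to
#' numeric, continuous values unchanged. No normalization happens at ingest;
#' the fitted combination weights absorb scale.
#'
#' @param records data.frame with columns `item_id`, `agent_id`,
#'   `chosen_label`, `confidence` and optional `score_*` / `ppl_*` columns.
#' @param truth data.frame with columns `item_id`, `true_label`, or a named
#'   integer vector keyed by item id.
#' @param agents data.frame with columns `agent_id`, `agent_type` (one of
#'   `"human_discrete"`, `"human_continuous"`, `"machine_scores"`,
#'   `"machine_perplexity"`) and `rating_levels` (required for
#'   `human_discrete`, `NA` otherwise).
#' @param n_classes number of classes `L >= 2`.
#' @param metadata free-form list (source tags, noise levels, ...).
#' @param check validate on construction and fail on any violation?
#' @return An object of class `judgment_panel`.
#' @seealso [validate_panel()], [read_panel()], [write_panel()]
#' @export
judgment_panel <- function(records, truth, agents, n_classes,
                           metadata = list(), check = TRUE) {
  if (!is.data.frame(records)) stop_ctx("`records` must be a data.frame")
  if (!is.data.frame(agents)) stop_ctx("`agents` must be a data.frame")
  n_classes <- as.integer(n_classes)
  if (is.na(n_classes) || n_classes < 2L) stop_ctx("`n_classes` must be >= 2")

  if (is.data.frame(truth)) {
    need <- setdiff(c("item_id", "true_label"), names(truth))
    if (length(need)) {
      stop_ctx("schema error: truth table missing column(s): ",
               paste(need, collapse = ", "))
    }
    tv <- as.integer(truth$true_label)
    names(tv) <- as.character(truth$item_id)
    truth <- tv
  } else {
    truth <- stats::setNames(as.integer(truth), names(truth))
  }
  if (anyDuplicated(names(truth))) stop_ctx("duplicate item_id in truth table")

  need <- setdiff(c("agent_id", "agent_type"), names(agents))
  if (length(need)) {
    stop_ctx("schema error: agents table missing column(s): ",
             paste(need, collapse = ", "))
  }
  if (!"rating_levels" %in% names(agents)) agents$rating_levels <- NA_integer_
  agents$agent_id <- as.character(agents$agent_id)
  agents$agent_type <- as.character(agents$agent_type)
  agents$rating_levels <- as.integer(agents$rating_levels)
  if (anyDuplicated(agents$agent_id)) stop_ctx("duplicate agent_id in agents table")

  need <- setdiff(c("item_id", "agent_id", "chosen_label", "confidence"),
                  names(records))
  if (length(need)) {
    stop_ctx("schema error: judgments table missing column(s): ",
             paste(need, collapse = ", "))
  }
  records$item_id <- as.character(records$item_id)
  records$agent_id <- as.character(records$agent_id)
  records$chosen_label <- as.integer(records$chosen_label)
  records$confidence <- as.numeric(records$confidence)
  rownames(records) <- NULL

  panel <- structure(
    list(
      n_items = length(truth),
      n_classes = n_classes,
      truth = truth,
      agents = agents,
      records = records,
      metadata = metadata
    ),
    class = "judgment_panel"
  )
  if (check) {
    bad <- validate_panel(panel)
    if (length(bad)) {
      stop_ctx("invalid judgment panel:\n  ", paste(bad, collapse = "\n  "))
    }
  }
  panel
}

score_cols <- function(panel) {
  cols <- paste0("score_", seq_len(panel$n_classes) - 1L)
  if (all(cols %in% names(panel$records))) cols else NULL
}

ppl_cols <- function(panel) {
  cols <- paste0("ppl_", seq_len(panel$n_classes) - 1L)
  if (all(cols %in% names(panel$records))) cols else NULL
}

agent_type_of <- function(panel, agent_id) {
  i <- match(agent_id, panel$agents$agent_id)
  if (is.na(i)) stop_ctx("unknown agent: ", agent_id)
  panel$agents$agent_type[i]
}

valid_agent_types <- c("human_discrete", "human_continuous",
                       "machine_scores", "machine_perplexity")

#' Validate a judgment panel
#'
#' Pure report of every invariant violation: references to undeclared agents
#' or items, out-of-range labels, negative confidences, probability-score
#' rows that do not sum to 1 or whose chosen label is not a maximal score,
#' and perplexity rows whose chosen label does not have the lowest
#' perplexity. Repeated calls on the same panel give identical reports;
#' nothing is raised.
#'
#' @param panel a [judgment_panel].
#' @return Character vector of violation descriptions, each naming the
#'   offending item/agent; empty when the panel is valid.
#' @export
validate_panel <- function(panel) {
  out <- character(0)
  rec <- panel$records
  L <- panel$n_classes
  agents <- panel$agents

  bad_type <- !agents$agent_type %in% valid_agent_types
  if (any(bad_type)) {
    out <- c(out, sprintf("agent %s: unknown agent_type '%s'",
                          agents$agent_id[bad_type], agents$agent_type[bad_type]))
  }
  needs_r <- agents$agent_type == "human_discrete"
  miss_r <- needs_r & (is.na(agents$rating_levels) | agents$rating_levels < 2L)
  if (any(miss_r)) {
    out <- c(out, sprintf("agent %s: human_discrete requires rating_levels >= 2",
                          agents$agent_id[miss_r]))
  }
  extra_r <- !needs_r & !is.na(agents$rating_levels)
  if (any(extra_r)) {
    out <- c(out, sprintf("agent %s: rating_levels only allowed for human_discrete",
                          agents$agent_id[extra_r]))
  }

  if (nrow(rec) == 0L) return(out)
  tag <- sprintf("record (item %s, agent %s)", rec$item_id, rec$agent_id)

  unk_agent <- !rec$agent_id %in% agents$agent_id
  if (any(unk_agent)) {
    out <- c(out, paste0(tag[unk_agent], ": references undeclared agent"))
  }
  unk_item <- !rec$item_id %in% names(panel$truth)
  if (any(unk_item)) {
    out <- c(out, paste0(tag[unk_item], ": references item without a truth label"))
  }
  bad_lab <- is.na(rec$chosen_label) | rec$chosen_label < 0L | rec$chosen_label >= L
  if (any(bad_lab)) {
    out <- c(out, paste0(tag[bad_lab], sprintf(": chosen_label outside 0..%d", L - 1L)))
  }
  bad_conf <- is.na(rec$confidence) | rec$confidence < 0
  if (any(bad_conf)) {
    out <- c(out, paste0(tag[bad_conf], ": confidence must be non-negative"))
  }

  sc <- score_cols(panel)
  if (!is.null(sc)) {
    S <- as.matrix(rec[, sc, drop = FALSE])
    has <- rowSums(is.na(S)) == 0L
    if (any(has)) {
      sums <- rowSums(S[has, , drop = FALSE])
      off <- which(has)[abs(sums - 1) > 1e-9]
      if (length(off)) {
        out <- c(out, paste0(tag[off], ": class scores must sum to 1"))
      }
      neg <- which(has)[apply(S[has, , drop = FALSE] < 0, 1L, any)]
      if (length(neg)) {
        out <- c(out, paste0(tag[neg], ": class scores must be non-negative"))
      }
      ok_lab <- !bad_lab & has
      if (any(ok_lab)) {
        idx <- which(ok_lab)
        chosen_val <- S[cbind(idx, rec$chosen_label[idx] + 1L)]
        mx <- apply(S[idx, , drop = FALSE], 1L, max)
        off <- idx[chosen_val < mx - 1e-12]
        if (length(off)) {
          out <- c(out, paste0(tag[off], ": chosen_label is not a maximal class score"))
        }
      }
    }
  }

  pc <- ppl_cols(panel)
  if (!is.null(pc)) {
    Q <- as.matrix(rec[, pc, drop = FALSE])
    has <- rowSums(is.na(Q)) == 0L
    neg <- which(has)[apply(Q[has, , drop = FALSE] < 0, 1L, any)]
    if (length(neg)) {
      out <- c(out, paste0(tag[neg], ": perplexities must be non-negative"))
    }
    ok_lab <- !bad_lab & has
    if (any(ok_lab)) {
      idx <- which(ok_lab)
      chosen_val <- Q[cbind(idx, rec$chosen_label[idx] + 1L)]
      mn <- apply(Q[idx, , drop = FALSE], 1L, min)
      off <- idx[chosen_val > mn + 1e-12]
      if (length(off)) {
        out <- c(out, paste0(tag[off], ": chosen_label does not have the lowest perplexity"))
      }
    }
  }

  # discrete humans must rate within their scale
  hd <- agents$agent_id[agents$agent_type == "human_discrete" & !is.na(agents$rating_levels)]
  if (length(hd)) {
    rl <- stats::setNames(agents$rating_levels, agents$agent_id)
    sel <- rec$agent_id %in% hd & !bad_conf
    off <- which(sel)[rec$confidence[sel] > rl[rec$agent_id[sel]] - 1L |
                        rec$confidence[sel] != floor(rec$confidence[sel])]
    if (length(off)) {
      out <- c(out, paste0(tag[off], ": discrete confidence must be an integer in 0..R-1"))
    }
  }
  out
}

#' @export
print.judgment_panel <- function(x, ...) {
  cat("Judgment panel:", x$n_items, "items,", x$n_classes, "classes,",
      nrow(x$records), "records\n")
  tab <- table(x$records$agent_id)
  for (a in x$agents$agent_id) {
    cat(sprintf("  %-14s %-18s %d records\n", a, agent_type_of(x, a),
                if (a %in% names(tab)) tab[[a]] else 0L))
  }
  invisible(x)
}

#' Read a judgment panel from CSV files
#'
#' Expects the three-file schema: `judgments.csv` (`item_id`, `agent_id`,
#' `chosen_label`, `confidence`, optional `score_0..score_{L-1}` and/or
#' `ppl_0..ppl_{L-1}`), `truth.csv` (`item_id`, `true_label`) and
#' `agents.csv` (`agent_id`, `agent_type`, `rating_levels`). Rows violating
#' panel invariants are rejected with an error naming each offender, never
#' silently dropped.
#'
#' @param judgments_path,truth_path,agents_path CSV file paths.
#' @param n_classes number of classes; inferred from score/ppl columns or
#'   the truth labels when `NULL`.
#' @param metadata optional list stored on the panel.
#' @return A validated [judgment_panel].
#' @export
read_panel <- function(judgments_path, truth_path, agents_path,
                       n_classes = NULL, metadata = list()) {
  for (p in c(judgments_path, truth_path, agents_path)) {
    if (!file.exists(p)) stop_ctx("file not found: ", p)
  }
  rec <- utils::read.csv(judgments_path, stringsAsFactors = FALSE)
  truth <- utils::read.csv(truth_path, stringsAsFactors = FALSE)
  agents <- utils::read.csv(agents_path, stringsAsFactors = FALSE)

  need <- setdiff(c("item_id", "agent_id", "chosen_label", "confidence"), names(rec))
  if (length(need)) {
    stop_ctx("schema error: judgments file missing column(s): ",
             paste(need, collapse = ", "))
  }
  need <- setdiff(c("item_id", "true_label"), names(truth))
  if (length(need)) {
    stop_ctx("schema error: truth file missing column(s): ",
             paste(need, collapse = ", "))
  }
  need <- setdiff(c("agent_id", "agent_type"), names(agents))
  if (length(need)) {
    stop_ctx("schema error: agents file missing column(s): ",
             paste(need, collapse = ", "))
  }
  if (is.null(n_classes)) {
    ns <- sum(grepl("^score_[0-9]+$", names(rec)))
    np <- sum(grepl("^ppl_[0-9]+$", names(rec)))
    n_classes <- max(ns, np, max(truth$true_label) + 1L, 2L)
  }
  judgment_panel(rec, truth, agents, n_classes, metadata = metadata)
}

#' Write a judgment panel to CSV files
#'
#' Inverse of [read_panel()]: emits `judgments.csv`, `truth.csv` and
#' `agents.csv` into `dir` with full numeric precision, so that
#' read-write-read round trips reproduce every field exactly.
#'
#' @param panel a [judgment_panel].
#' @param dir output directory (created if needed).
#' @return Invisibly, the three file paths.
#' @export
write_panel <- function(panel, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, c("judgments.csv", "truth.csv", "agents.csv"))

  rec <- panel$records
  num <- vapply(rec, is.double, logical(1))
  rec[num] <- lapply(rec[num], format_full)
  utils::write.csv(rec, paths[1], row.names = FALSE, quote = FALSE, na = "")

  truth <- data.frame(item_id = names(panel$truth),
                      true_label = unname(panel$truth))
  utils::write.csv(truth, paths[2], row.names = FALSE, quote = FALSE)
  utils::write.csv(panel$agents, paths[3], row.names = FALSE, quote = FALSE, na = "")
  invisible(paths)
}

#' Specify a team of agents and a combination rule
#'
#' @param members character vector of agent ids (at least one; the Bayesian
#'   combiner requires exactly two, its published form).
#' @param combiner one of `"logistic"`, `"bayesian"`, `"majority"`.
#' @param use_confidence when `FALSE`, every confidence magnitude is replaced
#'   by 1 and only the sign of each judgment is kept (the
#'   wisdom-of-the-crowds foil).
#' @param alpha optional named vector of per-member calibration-squashing
#'   strengths (see [calibration_transform()]); default identity for all.
#' @param interactions add pairwise product columns of member features
#'   (binary panels only).
#' @param poly_degree add polynomial columns `x^2..x^d` of member features
#'   when `> 1` (binary panels only).
#' @return An object of class `team_spec`.
#' @export
team_spec <- function(members, combiner = c("logistic", "bayesian", "majority"),
                      use_confidence = TRUE, alpha = NULL,
                      interactions = FALSE, poly_degree = 1L) {
  combiner <- match.arg(combiner)
  members <- as.character(members)
  if (length(members) < 1L) stop_ctx("a team needs at least one member")
  if (anyDuplicated(members)) stop_ctx("duplicate team members")
  if (combiner == "bayesian" && length(members) != 2L) {
    stop_ctx("the Bayesian combiner requires exactly two members")
  }
  if (!is.null(alpha)) {
    if (is.null(names(alpha)) || !all(names(alpha) %in% members)) {
      stop_ctx("`alpha` must be named by team members")
    }
    if (any(alpha < 0)) stop_ctx("`alpha` must be non-negative")
  }
  structure(list(members = members, combiner = combiner,
                 use_confidence = isTRUE(use_confidence), alpha = alpha,
                 interactions = isTRUE(interactions),
                 poly_degree = as.integer(poly_degree)),
            class = "team_spec")
}

#' @export
print.team_spec <- function(x, ...) {
  cat(sprintf("Team [%s] via %s combiner%s\n",
              paste(x$members, collapse = " + "), x$combiner,
              if (!x$use_confidence) " (no-confidence variant)" else ""))
  invisible(x)
}

as_team_spec <- function(team, combiner = "logistic") {
  if (inherits(team, "team_spec")) return(team)
  team_spec(team, combiner = combiner)
}
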