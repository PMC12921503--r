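# Signed-confidence predictors.
#
# Every team member contributes, per observation i and class j, a signed
# value x[i, j, k]: the magnitude is the member's confidence (a rating r for
# humans, the class score pi_j for probabilistic classifiers, |delta PPL|
# for language models) and the sign encodes whether class j was the member's
# choice. These signed values are the predictors of the logistic
# combination model.

#' Signed confidence of a human judgment
#'
#' Returns `+r` when `class_j` is the chosen label and `-r` otherwise, where
#' `r` is the rater's confidence on that trial.
#'
#' @param chosen_label 0-based chosen class.
#' @param confidence non-negative confidence `r`.
#' @param class_j 0-based class the feature is built for.
#' @param n_classes number of classes (bounds check).
#' @return Signed confidence, a scalar.
#' @export
signed_confidence_human <- function(chosen_label, confidence, class_j,
                                    n_classes = max(chosen_label, class_j) + 1L) {
  if (any(class_j < 0L) || any(class_j >= n_classes)) {
    stop_ctx("class_j outside 0..", n_classes - 1L)
  }
  if (any(confidence < 0)) stop_ctx("confidence must be non-negative")
  ifelse(chosen_label == class_j, confidence, -confidence)
}

#' Signed confidence of a probabilistic classifier
#'
#' Returns `+pi_j` when `class_j` is the chosen label and `-pi_j` otherwise:
#' each class keeps its own score magnitude, only the sign encodes the
#' choice.
#'
#' @param chosen_label 0-based chosen class.
#' @param class_scores per-class probability scores `pi` (length `L`).
#' @param class_j 0-based class the feature is built for.
#' @return Signed score, a scalar.
#' @export
signed_confidence_machine <- function(chosen_label, class_scores, class_j) {
  if (is.null(class_scores) || anyNA(class_scores)) {
    stop_ctx("class_scores missing for a machine_scores record")
  }
  L <- length(class_scores)
  if (any(class_j < 0L) || any(class_j >= L)) stop_ctx("class_j outside 0..", L - 1L)
  s <- class_scores[class_j + 1L]
  ifelse(chosen_label == class_j, s, -s)
}

#' Choice and confidence from a perplexity pair
#'
#' A language model presented with two candidate texts chooses the one with
#' the lower perplexity; its confidence is the absolute perplexity
#' difference `|q_0 - q_1|`. Exact ties resolve deterministically to label 0
#' and are flagged.
#'
#' @param perplexities length-2 non-negative vector `(q_0, q_1)`.
#' @return List with `chosen_label`, `confidence` and logical `tie`.
#' @export
llm_choice_and_confidence <- function(perplexities) {
  if (length(perplexities) != 2L) stop_ctx("expected exactly two perplexities")
  if (anyNA(perplexities) || any(!is.finite(perplexities))) {
    stop_ctx("perplexities must be finite")
  }
  if (any(perplexities < 0)) stop_ctx("perplexities must be non-negative")
  tie <- perplexities[1] == perplexities[2]
  list(chosen_label = if (tie) 0L else as.integer(which.min(perplexities)) - 1L,
       confidence = abs(perplexities[1] - perplexities[2]),
       tie = tie)
}

#' Convert perplexities to probability scores
#'
#' `pi = Softmax(-q)`: lower perplexity maps to higher probability, and the
#' result is invariant to adding a constant to all perplexities.
#'
#' @param perplexities length-`L` finite vector.
#' @return Probability vector summing to 1.
#' @export
perplexity_to_scores <- function(perplexities) {
  if (anyNA(perplexities) || any(!is.finite(perplexities))) {
    stop_ctx("perplexities must be finite")
  }
  z <- -perplexities
  e <- exp(z - max(z))
  e / sum(e)
}

#' Calibration-squashing transform of a confidence magnitude
#'
#' `f(x) = 1 + (x - 1) / (1 + alpha * |x - 1|)`. For `alpha = 0` this is the
#' identity; as `alpha` grows every magnitude is squashed toward 1, so a
#' member whose confidence is uninformative degrades gracefully to a
#' sign-only (vote) predictor instead of injecting noise.
#'
#' @param x confidence magnitude(s).
#' @param alpha non-negative squashing strength.
#' @return Transformed magnitude(s); for `x >= 1` the output lies in
#'   `[1, x]`, and `f(1) = 1` for every `alpha`.
#' @export
calibration_transform <- function(x, alpha) {
  if (length(alpha) != 1L || is.na(alpha) || alpha < 0) {
    stop_ctx("`alpha` must be a single non-negative number")
  }
  1 + (x - 1) / (1 + alpha * abs(x - 1))
}

#' Pair the records of several team members into observations
#'
#' One observation supplies, for a single item, one record from every team
#' member. A member with several records on an item (e.g. a pooled human
#' population) yields one observation per record; members with one record
#' per item are repeated across them.
#'
#' @param panel a [judgment_panel].
#' @param members character vector of agent ids.
#' @param on_missing `"error"` (name the item and member) or `"drop"`
#'   (exclude the item with a warning).
#' @return data.frame with `item_id` and one record-row-index column per
#'   member (named `rec.<agent_id>`).
#' @export
pair_observations <- function(panel, members, on_missing = c("error", "drop")) {
  on_missing <- match.arg(on_missing)
  members <- as.character(members)
  unknown <- setdiff(members, panel$agents$agent_id)
  if (length(unknown)) stop_ctx("unknown agent(s): ", paste(unknown, collapse = ", "))

  items <- names(panel$truth)
  by_agent <- lapply(members, function(a) {
    idx <- which(panel$records$agent_id == a)
    per_item <- split(idx, factor(panel$records$item_id[idx], levels = items))
    # canonical within-item order by record content, so that observation
    # pairing does not depend on how the records happen to be listed
    lapply(per_item, function(ii) {
      ii[order(panel$records$chosen_label[ii], panel$records$confidence[ii])]
    })
  })
  names(by_agent) <- members

  rows <- vector("list", length(items))
  dropped <- character(0)
  for (t in seq_along(items)) {
    per_member <- lapply(by_agent, function(m) m[[t]])
    empty <- lengths(per_member) == 0L
    if (any(empty)) {
      if (on_missing == "error") {
        stop_ctx("pairing error: item ", items[t], " has no record for member(s) ",
                 paste(members[empty], collapse = ", "))
      }
      dropped <- c(dropped, items[t])
      next
    }
    grid <- expand.grid(rev(per_member), KEEP.OUT.ATTRS = FALSE)
    grid <- grid[, rev(seq_along(per_member)), drop = FALSE]
    names(grid) <- paste0("rec.", members)
    grid$item_id <- items[t]
    rows[[t]] <- grid
  }
  if (length(dropped)) {
    warning("excluded item(s) without records for all members: ",
            paste(dropped, collapse = ", "), call. = FALSE)
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out)) out <- data.frame(item_id = character(0))
  rownames(out) <- NULL
  out[, c("item_id", paste0("rec.", members)), drop = FALSE]
}

# n x K matrix of one class's signed values, robust to n == 1 or K == 1
class_slice <- function(X, class_idx) {
  out <- X[, class_idx, , drop = FALSE]
  dim(out) <- c(dim(X)[1L], dim(X)[3L])
  out
}

member_magnitudes <- function(panel, member, rec_idx) {
  # returns n x L matrix of unsigned magnitudes and the chosen labels
  type <- agent_type_of(panel, member)
  rec <- panel$records[rec_idx, , drop = FALSE]
  L <- panel$n_classes
  chosen <- rec$chosen_label
  if (type %in% c("human_discrete", "human_continuous", "machine_perplexity")) {
    mag <- matrix(rec$confidence, nrow = nrow(rec), ncol = L)
  } else if (type == "machine_scores") {
    sc <- score_cols(panel)
    if (is.null(sc)) stop_ctx("panel has no score columns for machine_scores member ", member)
    mag <- as.matrix(rec[, sc, drop = FALSE])
    if (anyNA(mag)) stop_ctx("missing class scores for member ", member)
  } else {
    stop_ctx("unsupported agent type: ", type)
  }
  list(mag = mag, chosen = chosen)
}

#' Build the signed-confidence feature matrix for a team
#'
#' Assembles, for every observation (see [pair_observations()]) and every
#' team member, the per-class signed values that feed the logistic
#' combination model. Per-member calibration squashing
#' ([calibration_transform()]) is applied to the magnitudes before signing;
#' with `use_confidence` off every magnitude is replaced by 1 (signs
#' preserved). Optional interaction (`x_H * x_M`) and polynomial (`x^2`,
#' ...) columns are appended for binary panels.
#'
#' @param panel a [judgment_panel].
#' @param team a [team_spec] (or character vector of members).
#' @param observations optional observation pairing from
#'   [pair_observations()]; computed if `NULL`.
#' @return Object of class `feature_matrix`: list with the `n_obs x L x K`
#'   signed array `X`, optional `extras` matrix, `members`, `n_classes`,
#'   per-observation `items` and the `observations` pairing.
#' @export
build_feature_matrix <- function(panel, team, observations = NULL) {
  team <- as_team_spec(team)
  members <- team$members
  if (is.null(observations)) observations <- pair_observations(panel, members)
  n <- nrow(observations)
  L <- panel$n_classes
  K <- length(members)
  X <- array(0, dim = c(n, L, K), dimnames = list(NULL, NULL, members))

  for (k in seq_len(K)) {
    mm <- member_magnitudes(panel, members[k], observations[[paste0("rec.", members[k])]])
    mag <- mm$mag
    a <- team$alpha[[members[k]]]
    if (!is.null(a) && a > 0) mag <- calibration_transform(mag, a)
    if (!team$use_confidence) mag[] <- 1
    sign_m <- matrix(-1, nrow = n, ncol = L)
    if (n > 0) sign_m[cbind(seq_len(n), mm$chosen + 1L)] <- 1
    X[, , k] <- mag * sign_m
  }

  extras <- NULL
  if (team$interactions || team$poly_degree > 1L) {
    if (L != 2L) stop_ctx("interaction/polynomial columns require a binary panel")
    x0 <- class_slice(X, 1L)
    colnames(x0) <- members
    cols <- list()
    if (team$interactions && K >= 2L) {
      for (i in seq_len(K - 1L)) for (j in seq((i + 1L), K)) {
        cols[[paste0(members[i], ":", members[j])]] <- x0[, i] * x0[, j]
      }
    }
    if (team$poly_degree > 1L) {
      for (d in 2:team$poly_degree) for (k in seq_len(K)) {
        cols[[paste0(members[k], "^", d)]] <- x0[, k]^d
      }
    }
    if (length(cols)) extras <- do.call(cbind, cols)
  }

  structure(list(X = X, extras = extras, members = members, n_classes = L,
                 items = observations$item_id, observations = observations,
                 team = team),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat("Feature matrix:", dim(x$X)[1], "observations x", x$n_classes,
      "classes x", length(x$members), "members",
      if (!is.null(x$extras)) paste0("(+", ncol(x$extras), " extra columns)") else "",
      "\n")
  invisible(x)
}

subset_features <- function(fm, idx) {
  structure(list(X = fm$X[idx, , , drop = FALSE],
                 extras = if (is.null(fm$extras)) NULL else fm$extras[idx, , drop = FALSE],
                 members = fm$members, n_classes = fm$n_classes,
                 items = fm$items[idx],
                 observations = fm$observations[idx, , drop = FALSE],
                 team = fm$team),
            class = "feature_matrix")
}

# true label of each observation's item
feature_outcomes <- function(panel, fm) {
  unname(panel$truth[fm$items])
}
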