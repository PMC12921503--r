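# Internal helpers shared across the package.

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so seeded internals never disturb the
#' caller's random stream.
#' @noRd
with_seed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1L)
  }
  old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  expr
}

# Gauss-Hermite nodes/weights rescaled for E[f(Z)], Z ~ N(0, 1).
gh_normal <- function(n) {
  gh <- pracma::gaussHermite(n)
  list(x = gh$x * sqrt(2), w = gh$w / sqrt(pi))
}

# log(sum(exp(x))) without overflow
logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# Numeric columns written with full precision so that CSV round trips are
# bitwise idempotent.
format_full <- function(x) {
  out <- vapply(x, function(v) {
    if (is.na(v)) NA_character_ else sprintf("%.17g", v)
  }, character(1))
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_ctx <- function(...) stop(..., call. = FALSE)
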