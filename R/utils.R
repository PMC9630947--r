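#' @keywords internal
"_PACKAGE"

# Probability clipping bound applied to every emitted propensity score and
# before any logit transform.
SCORE_EPS <- 1e-6

logit <- function(p) log(p / (1 - p))

expit <- function(x) 1 / (1 + exp(-x))

clip_prob <- function(p, eps = SCORE_EPS) pmin(pmax(p, eps), 1 - eps)

#' Evaluate an expression with a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so seeded package internals do not
#' disturb the caller's random stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  expr
}

# Deterministic per-stage seed derivation: stage k of a run seeded with s uses
# s * 131 + k (mod 2^31 - 2), + 1 so it is never 0. Documented in the
# pipeline help page so stages can be re-run in isolation.
stage_seed <- function(global_seed, stage) {
  as.integer((as.double(global_seed) * 131 + stage) %% (.Machine$integer.max - 1L)) + 1L
}

# 17-significant-digit formatting for machine-readable CSV output.
fmt_machine <- function(x) {
  if (is.double(x)) sprintf("%.17g", x) else x
}

`%||%` <- function(a, b) if (is.null(a)) b else a
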