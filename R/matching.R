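#' Matching specification
#'
#' @param K controls per treated subject (>= 1).
#' @param with_replacement reuse controls across treated subjects. The default
#'   `TRUE` follows the K:1 nearest-neighbor-with-replacement scheme of the
#'   reported analyses; `FALSE` gives classical greedy 1-1 style matching
#'   where a used control leaves the pool.
#' @param caliper a positive number, or `"auto"` for 0.2 standard deviations
#'   of the scores on the chosen distance scale (see [auto_caliper()]).
#' @param distance_scale match on the `"logit"` of the score (default) or the
#'   `"raw"` probability.
#' @param order_policy order in which treated subjects claim controls:
#'   `"descending_score"` (default), `"data_order"`, or `"random"` (seeded).
#' @param strict_k require the full K in-caliper controls: a treated subject
#'   finding fewer gets no pairs at all. Default `FALSE` keeps partial matches
#'   (1..K controls).
#' @param seed integer seed, used only when `order_policy = "random"`.
#' @return An object of class `match_spec`.
#' @export
match_spec <- function(K = 1L, with_replacement = TRUE, caliper = "auto",
                       distance_scale = c("logit", "raw"),
                       order_policy = c("descending_score", "data_order",
                                        "random"),
                       strict_k = FALSE, seed = 1L) {
  distance_scale <- match.arg(distance_scale)
  order_policy <- match.arg(order_policy)
  if (K < 1L) stop("K must be >= 1", call. = FALSE)
  if (is.numeric(caliper)) {
    if (caliper <= 0) stop("numeric caliper must be > 0", call. = FALSE)
  } else if (!identical(caliper, "auto")) {
    stop("caliper must be a positive number or \"auto\"", call. = FALSE)
  }
  structure(list(K = as.integer(K), with_replacement = with_replacement,
                 caliper = caliper, distance_scale = distance_scale,
                 order_policy = order_policy, strict_k = strict_k,
                 seed = as.integer(seed)),
            class = "match_spec")
}

#' Default caliper width
#'
#' 0.2 times the sample standard deviation (n-1 denominator) of the scores on
#' the chosen distance scale — the standard caliper recommendation for
#' propensity matching.
#'
#' @param scores propensity scores in (0, 1).
#' @param scale `"logit"` (standard deviation of the logit-transformed scores)
#'   or `"raw"`.
#' @return A positive caliper width.
#' @export
auto_caliper <- function(scores, scale = c("logit", "raw")) {
  scale <- match.arg(scale)
  if (length(scores) < 2L) stop("need at least 2 scores", call. = FALSE)
  s <- if (scale == "logit") logit(clip_prob(scores)) else scores
  cal <- 0.2 * stats::sd(s)
  if (!is.finite(cal) || cal <= 0) {
    stop("degenerate scores: zero variance, caliper undefined", call. = FALSE)
  }
  cal
}

#' Greedy K:1 nearest-neighbor caliper matching
#'
#' Treated subjects, taken in the order given by `spec$order_policy`, each
#' claim the K nearest controls (by absolute score distance on the chosen
#' scale) lying within the caliper; without replacement a claimed control
#' leaves the pool. A treated subject with no in-caliper control receives no
#' pairs and will be labelled "out". Distance ties are broken by the lower
#' control subject id. Deterministic given the spec (and its seed when
#' `order_policy = "random"`).
#'
#' @param scores propensity scores in (0, 1), one per subject.
#' @param treat 0/1 treatment vector.
#' @param spec a [match_spec()].
#' @return An object of class `match_result`: `pairs` (data.frame
#'   `treated_id`, `control_id`, `distance`; subject ids are 0-based
#'   positions), `inclusion` (factor out/in per subject), the resolved
#'   `caliper`, and counts `n_matched_treated`, `n_unmatched_treated`,
#'   `n_distinct_controls_used`.
#' @export
nearest_neighbor_match <- function(scores, treat, spec = match_spec()) {
  n <- length(scores)
  treat <- as.integer(treat)
  stopifnot(length(treat) == n, all(treat %in% c(0L, 1L)))
  if (sum(treat) == 0L || sum(treat) == n) {
    stop("both treatment groups must be non-empty", call. = FALSE)
  }
  if (any(scores <= 0 | scores >= 1)) {
    stop("scores must lie strictly inside (0, 1)", call. = FALSE)
  }
  w <- if (spec$distance_scale == "logit") logit(clip_prob(scores)) else scores
  caliper <- if (identical(spec$caliper, "auto")) {
    auto_caliper(scores, spec$distance_scale)
  } else {
    spec$caliper
  }
  treated <- which(treat == 1L)
  controls <- which(treat == 0L)
  treated <- switch(spec$order_policy,
    descending_score = treated[order(-w[treated], treated)],
    data_order = treated,
    random = with_seed(spec$seed, treated[sample.int(length(treated))]))
  available <- rep(TRUE, n)    # indexed by subject position; controls only
  pairs_t <- integer(0); pairs_c <- integer(0); pairs_d <- numeric(0)
  for (t in treated) {
    pool <- if (spec$with_replacement) controls else controls[available[controls]]
    if (!length(pool)) next
    d <- abs(w[pool] - w[t])
    elig <- d <= caliper
    if (!any(elig)) next
    cand <- pool[elig]
    dc <- d[elig]
    o <- order(dc, cand)
    take <- seq_len(min(spec$K, length(cand)))
    if (spec$strict_k && length(cand) < spec$K) next
    sel <- o[take]
    pairs_t <- c(pairs_t, rep(t, length(sel)))
    pairs_c <- c(pairs_c, cand[sel])
    pairs_d <- c(pairs_d, dc[sel])
    if (!spec$with_replacement) available[cand[sel]] <- FALSE
  }
  pairs <- data.frame(treated_id = pairs_t - 1L, control_id = pairs_c - 1L,
                      distance = pairs_d)
  res <- structure(list(pairs = pairs, caliper = caliper,
                        distance_scale = spec$distance_scale,
                        spec = spec, n = n,
                        n_matched_treated = length(unique(pairs_t)),
                        n_unmatched_treated = sum(treat) - length(unique(pairs_t)),
                        n_distinct_controls_used = length(unique(pairs_c))),
                   class = "match_result")
  res$inclusion <- label_inclusion(res, n)
  res
}

#' Label every subject matched ("in") or unmatched ("out")
#'
#' A subject is "in" iff it appears in at least one matched pair, as treated
#' or as control (a control reused under replacement counts once); all other
#' subjects are "out". The labels partition the cohort.
#'
#' @param match_result a [nearest_neighbor_match()] result (or anything with a
#'   `pairs` data.frame of 0-based `treated_id`/`control_id`).
#' @param n cohort size.
#' @return Factor of length `n` with levels `c("out", "in")`; position `i`
#'   corresponds to subject id `i - 1`.
#' @export
label_inclusion <- function(match_result, n) {
  ids <- unique(c(match_result$pairs$treated_id, match_result$pairs$control_id))
  if (length(ids) && any(ids < 0 | ids >= n)) {
    stop("pair ids must lie in [0, n)", call. = FALSE)
  }
  lab <- rep("out", n)
  lab[ids + 1L] <- "in"
  factor(lab, levels = c("out", "in"))
}

#' @export
print.match_result <- function(x, ...) {
  cat(sprintf(paste0("Match result: %d pairs (K = %d, %s replacement, ",
                     "caliper %.4g on %s scale)\n"),
              nrow(x$pairs), x$spec$K,
              if (x$spec$with_replacement) "with" else "without",
              x$caliper, x$distance_scale))
  cat(sprintf("  treated matched %d, unmatched %d; distinct controls used %d\n",
              x$n_matched_treated, x$n_unmatched_treated,
              x$n_distinct_controls_used))
  cat(sprintf("  inclusion: %d in / %d out of %d subjects\n",
              sum(x$inclusion == "in"), sum(x$inclusion == "out"), x$n))
  invisible(x)
}

#' Write matched pairs / inclusion labels as CSV
#'
#' @param match_result a `match_result`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_pairs <- function(match_result, path) {
  out <- match_result$pairs
  out$distance <- fmt_machine(out$distance)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_pairs
#' @export
write_labels <- function(match_result, path) {
  utils::write.csv(data.frame(subject_id = seq_len(match_result$n) - 1L,
                              label = as.character(match_result$inclusion)),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
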