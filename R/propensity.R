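# Build a covariate schema by inspecting a data.frame (numeric -> continuous,
# factor/character -> categorical with observed levels).
schema_from_data <- function(data, covariates) {
  lapply(covariates, function(nm) {
    x <- data[[nm]]
    if (is.null(x)) stop(sprintf("column '%s' missing from data", nm),
                         call. = FALSE)
    if (is.numeric(x)) {
      structure(list(name = nm, kind = "continuous"), class = "me_covariate")
    } else {
      lev <- if (is.factor(x)) levels(x) else sort(unique(as.character(x)))
      structure(list(name = nm, kind = "categorical", levels = lev,
                     probs = rep(1 / length(lev), length(lev))),
                class = "me_covariate")
    }
  })
}

default_covariates <- function(data, treatment) {
  setdiff(names(data), c(treatment, "subject_id", "true_score"))
}

#' Maximum-likelihood logistic regression via IRLS
#'
#' Iteratively reweighted least squares with step-halving on a likelihood
#' decrease. Convergence is declared when every component of the score
#' equation `X'(y - p)` is below `tol` in absolute value. Perfect separation
#' (diverging coefficients) stops the iteration with a warning; fitted scores
#' are still returned, clipped to `[1e-6, 1 - 1e-6]`.
#'
#' @param design numeric matrix of covariate columns (no intercept column; one
#'   is added internally).
#' @param treat 0/1 treatment vector, one per design row; both groups must be
#'   non-empty.
#' @param max_iter maximum IRLS iterations.
#' @param tol convergence tolerance on the score equations.
#' @return An object of class `propensity_fit` with `method = "logistic"`,
#'   `scores`, named `coefficients` (intercept first), `converged`,
#'   `iterations` and a `separation` flag.
#' @export
fit_logistic <- function(design, treat, max_iter = 50L, tol = 1e-8) {
  design <- as.matrix(design)
  storage.mode(design) <- "double"
  y <- as.numeric(treat)
  if (nrow(design) != length(y)) {
    stop("design rows must equal length(treat)", call. = FALSE)
  }
  if (!all(y %in% c(0, 1)) || sum(y) == 0 || sum(y) == length(y)) {
    stop("treat must be 0/1 with both groups non-empty", call. = FALSE)
  }
  if (is.null(colnames(design)) && ncol(design) > 0) {
    colnames(design) <- paste0("x", seq_len(ncol(design)))
  }
  X <- cbind("(Intercept)" = 1, design)
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    bad <- colnames(X)[qx$pivot[(qx$rank + 1L):ncol(X)]]
    stop(sprintf("design is rank-deficient; collinear column(s): %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  beta <- numeric(ncol(X))
  loglik <- function(b) {
    eta <- drop(X %*% b)
    sum(y * eta - log1p(exp(eta)))
  }
  ll <- loglik(beta)
  converged <- FALSE
  separation <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    eta <- drop(X %*% beta)
    p <- expit(eta)
    score <- drop(crossprod(X, y - p))
    if (max(abs(score)) < tol) {
      converged <- TRUE
      break
    }
    w <- pmax(p * (1 - p), 1e-10)
    delta <- solve(crossprod(X, X * w), score)
    step <- 1
    repeat {
      cand <- beta + step * delta
      ll_new <- loglik(cand)
      if (ll_new >= ll - 1e-12 || step < 2^-30) break
      step <- step / 2
    }
    beta <- cand
    ll <- ll_new
    if (sqrt(sum(beta^2)) > 1e4 || max(abs(drop(X %*% beta))) > 30) {
      separation <- TRUE
      warning("possible perfect separation: coefficients diverging; ",
              "scores returned clipped", call. = FALSE)
      break
    }
  }
  p_fit <- expit(drop(X %*% beta))
  if (!separation && any(p_fit < tol | p_fit > 1 - tol)) {
    # fitted probabilities numerically 0/1: classic symptom of separation
    separation <- TRUE
    warning("possible perfect separation: fitted probabilities numerically ",
            "0 or 1; scores returned clipped", call. = FALSE)
  }
  scores <- clip_prob(p_fit)
  names(beta) <- colnames(X)
  new_propensity_fit("logistic", scores, coefficients = beta,
                     converged = converged, iterations = iter,
                     separation = separation)
}

new_propensity_fit <- function(method, scores, ...) {
  structure(c(list(method = method, scores = clip_prob(scores)), list(...)),
            class = "propensity_fit")
}

#' Classification-tree propensity scores
#'
#' Grows a tree for treatment vs covariates, prunes it at the complexity
#' parameter minimizing the cross-validated misclassification error, and
#' scores each subject with the treated fraction of its terminal node. When no
#' covariate separates treatment the tree is a root stump and every subject
#' receives the overall treated fraction.
#'
#' @param data data.frame holding the covariates.
#' @param treat 0/1 treatment vector.
#' @param covariates character vector of covariate columns; default: all
#'   columns except the bookkeeping ones.
#' @param control a [tree_control()].
#' @return A `propensity_fit` with `method = "tree"`, the pruned `tree`, the
#'   `cv` curve and the selected `cp`.
#' @export
fit_tree_propensity <- function(data, treat, covariates = NULL,
                                control = tree_control()) {
  covariates <- covariates %||% default_covariates(data, "T")
  y <- factor(as.integer(treat), levels = c("0", "1"))
  cv <- cross_validated_error(data[covariates], y, control)
  cp <- select_cp(cv, "min")
  tree <- prune_tree(attr(cv, "tree"), cp)
  scores <- clip_prob(predict(tree, newdata = data[covariates], type = "prob"))
  new_propensity_fit("tree", scores, tree = tree, cv = cv, cp = cp,
                     converged = TRUE, iterations = 1L)
}

#' Bagged-tree propensity scores
#'
#' Bootstrap-aggregated classification trees with per-split feature
#' subsampling (a random-forest-style estimator built on the package's own
#' tree engine). Each subject's score is the mean over trees of its terminal
#' node's treated fraction. Deterministic given `seed`.
#'
#' @inheritParams fit_tree_propensity
#' @param n_trees number of trees (>= 1).
#' @param mtry covariates considered at each split (1..number of covariates).
#' @param seed integer seed.
#' @param bootstrap resample subjects with replacement per tree (disable to
#'   fit every tree on the full sample).
#' @return A `propensity_fit` with `method = "forest"` and the list of trees.
#' @export
fit_bagged_trees <- function(data, treat, covariates = NULL, n_trees = 100L,
                             mtry = NULL, control = tree_control(),
                             seed = 1L, bootstrap = TRUE) {
  covariates <- covariates %||% default_covariates(data, "T")
  if (n_trees < 1L) stop("n_trees must be >= 1", call. = FALSE)
  mtry <- mtry %||% length(covariates)
  if (mtry < 1L || mtry > length(covariates)) {
    stop("mtry must be between 1 and the number of covariates", call. = FALSE)
  }
  X <- data[covariates]
  y <- factor(as.integer(treat), levels = c("0", "1"))
  n <- nrow(X)
  trees <- vector("list", n_trees)
  score_sum <- numeric(n)
  with_seed(seed, {
    for (b in seq_len(n_trees)) {
      idx <- if (bootstrap) sample.int(n, n, replace = TRUE) else seq_len(n)
      trees[[b]] <- grow_tree(X[idx, , drop = FALSE], y[idx], control,
                              mtry = if (mtry < length(covariates)) mtry else NULL)
      score_sum <- score_sum + predict(trees[[b]], newdata = X, type = "prob")
    }
  })
  new_propensity_fit("forest", score_sum / n_trees, trees = trees,
                     n_trees = n_trees, mtry = mtry, seed = seed,
                     converged = TRUE, iterations = n_trees)
}

#' Import externally computed propensity scores
#'
#' Accepts scores from estimators not implemented natively (e.g. covariate-
#' balancing, SVM, or boosting-based scores) via a CSV with columns
#' `subject_id` (0-based) and `score`, covering every subject exactly once.
#'
#' @param scores a data.frame with columns `subject_id`, `score`, or a path to
#'   such a CSV.
#' @param n cohort size the scores must cover.
#' @return A `propensity_fit` with `method = "external"`, scores ordered by
#'   `subject_id`.
#' @export
external_scores <- function(scores, n) {
  if (is.character(scores)) {
    scores <- utils::read.csv(scores, stringsAsFactors = FALSE)
  }
  if (!all(c("subject_id", "score") %in% names(scores))) {
    stop("external scores need columns subject_id, score", call. = FALSE)
  }
  expect_ids <- seq_len(n) - 1L
  if (nrow(scores) != n || !setequal(scores$subject_id, expect_ids) ||
      anyDuplicated(scores$subject_id)) {
    stop("external scores must cover every subject exactly once", call. = FALSE)
  }
  if (any(scores$score <= 0 | scores$score >= 1)) {
    stop("external scores must lie strictly inside (0, 1)", call. = FALSE)
  }
  s <- scores$score[order(scores$subject_id)]
  new_propensity_fit("external", s, converged = TRUE, iterations = 0L)
}

#' Fit a propensity-score model
#'
#' Front door over the package's estimators: `"logistic"` (maximum-likelihood
#' via IRLS on the dummy-coded design), `"tree"` (cross-validation-pruned
#' classification tree), `"forest"` (bagged trees with per-split feature
#' subsampling), or `"external"` (scores computed elsewhere).
#'
#' @param data cohort data.frame.
#' @param treatment name of the 0/1 treatment column.
#' @param covariates covariate column names; default: everything except the
#'   treatment and bookkeeping columns.
#' @param method estimator.
#' @param control [tree_control()] for tree/forest.
#' @param scores external scores (data.frame or CSV path) for
#'   `method = "external"`.
#' @param ... passed to the underlying estimator.
#' @return A `propensity_fit`.
#' @export
fit_propensity <- function(data, treatment = "T", covariates = NULL,
                           method = c("logistic", "tree", "forest", "external"),
                           control = tree_control(), scores = NULL, ...) {
  method <- match.arg(method)
  covariates <- covariates %||% default_covariates(data, treatment)
  treat <- data[[treatment]]
  if (is.null(treat)) {
    stop(sprintf("treatment column '%s' missing", treatment), call. = FALSE)
  }
  switch(method,
    logistic = {
      X <- encode_design(data, schema_from_data(data, covariates))
      fit_logistic(X, treat, ...)
    },
    tree = fit_tree_propensity(data, treat, covariates, control),
    forest = fit_bagged_trees(data, treat, covariates, control = control, ...),
    external = external_scores(scores, nrow(data))
  )
}

#' @export
print.propensity_fit <- function(x, ...) {
  cat(sprintf("Propensity fit (%s): n = %d, score range [%.4f, %.4f]\n",
              x$method, length(x$scores), min(x$scores), max(x$scores)))
  if (x$method == "logistic") {
    cat(sprintf("  converged: %s after %d iteration(s)%s\n", x$converged,
                x$iterations, if (isTRUE(x$separation)) " (separation!)" else ""))
  }
  invisible(x)
}

#' @export
coef.propensity_fit <- function(object, ...) object$coefficients

#' @export
fitted.propensity_fit <- function(object, ...) object$scores
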