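#' Fit a treatment-relevance explainer
#'
#' The package's central model. Runs the full diagnostic chain on a cohort:
#' (1) estimate propensity scores, (2) greedy K:1 nearest-neighbor caliper
#' matching, (3) label every subject "in" (matched) or "out" (unmatched),
#' (4) fit a cross-validation-pruned classification tree for the probability
#' of inclusion — the population-level explainer — and (5) build the
#' characteristics-by-match-status balance table. Individual-level local
#' surrogate explanations are computed on demand with [explain_subjects()].
#'
#' @param data cohort data.frame (e.g. from [generate_cohort()] or
#'   [read_cohort()]).
#' @param treatment name of the 0/1 treatment column.
#' @param covariates covariate columns; default: everything except the
#'   treatment, `subject_id` and `true_score`.
#' @param method propensity estimator: `"logistic"`, `"tree"`, `"forest"` or
#'   `"external"`.
#' @param match a [match_spec()].
#' @param control a [tree_control()] for the tree estimator and the explainer.
#' @param scores external scores (data.frame or CSV path) when
#'   `method = "external"`.
#' @param ... passed to the propensity estimator.
#' @return An object of class `relevance_fit`: `propensity`
#'   (`propensity_fit`), `match` (`match_result`), `inclusion` (out/in
#'   factor), `explainer` (pruned `cart_tree`), `balance` (`balance_table`),
#'   plus the data and column bookkeeping used by the methods.
#' @seealso [predict.relevance_fit()], [plot.relevance_fit()],
#'   [explain_subjects()], [run_pipeline()].
#' @examples
#' cfg <- cohort_preset("hn_ncdb", n = 600, seed = 7)
#' cohort <- generate_cohort(cfg)
#' fit <- treatment_relevance(cohort, control = tree_control(n_folds = 5))
#' fit
#' @export
treatment_relevance <- function(data, treatment = "T", covariates = NULL,
                                method = c("logistic", "tree", "forest",
                                           "external"),
                                match = match_spec(),
                                control = tree_control(), scores = NULL, ...) {
  method <- match.arg(method)
  covariates <- covariates %||% default_covariates(data, treatment)
  propensity <- fit_propensity(data, treatment, covariates, method,
                               control = control, scores = scores, ...)
  mres <- nearest_neighbor_match(propensity$scores, data[[treatment]], match)
  inclusion <- mres$inclusion
  explainer <- fit_population_explainer(data, inclusion, covariates, control)
  balance <- if (all(inclusion == "in") || all(inclusion == "out")) {
    NULL
  } else {
    characteristics_table(data, inclusion, covariates)
  }
  structure(list(propensity = propensity, match = mres,
                 inclusion = inclusion, explainer = explainer,
                 balance = balance, data = data, treatment = treatment,
                 covariates = covariates, method = method,
                 control = control, call = match.call()),
            class = "relevance_fit")
}

#' @export
print.relevance_fit <- function(x, ...) {
  cat("Treatment-relevance explainer\n")
  cat(sprintf("  propensity method: %s; matching: K = %d, %s replacement, caliper %.4g (%s scale)\n",
              x$method, x$match$spec$K,
              if (x$match$spec$with_replacement) "with" else "without",
              x$match$caliper, x$match$distance_scale))
  cat(sprintf("  inclusion: %d in / %d out of %d subjects\n",
              sum(x$inclusion == "in"), sum(x$inclusion == "out"),
              length(x$inclusion)))
  if (isTRUE(attr(x$explainer, "degenerate"))) {
    cat("  explainer: degenerate (single-class labels) - root stump\n")
  } else {
    cat(sprintf("  explainer: %d leaves after pruning at cp = %.4g\n",
                n_leaves(x$explainer), attr(x$explainer, "cp")))
  }
  invisible(x)
}

#' @export
summary.relevance_fit <- function(object, ...) {
  print(object)
  cat("\nPopulation-level explainer:\n")
  print(object$explainer)
  if (!is.null(object$balance)) {
    cat("\n")
    print(object$balance)
  }
  invisible(object)
}

#' Predict inclusion probability for new subjects
#'
#' Routes rows through the fitted population-level explainer tree.
#'
#' @param object a `relevance_fit`.
#' @param newdata data.frame of covariate rows; defaults to the training
#'   cohort.
#' @param type `"prob"` (probability of "in"), `"label"`, or `"both"`.
#' @param ... unused.
#' @return See [predict.cart_tree()].
#' @export
predict.relevance_fit <- function(object, newdata = NULL,
                                  type = c("prob", "label", "both"), ...) {
  newdata <- newdata %||% object$data
  predict(object$explainer, newdata = newdata, type = match.arg(type))
}

#' @export
plot.relevance_fit <- function(x, ...) plot(x$explainer, ...)

# pick one correctly-classified subject per inclusion group (lowest id);
# groups with no correct classification contribute nothing
auto_explain_ids <- function(fit) {
  pred <- predict(fit$explainer, newdata = fit$data, type = "label")
  correct <- pred == as.character(fit$inclusion)
  ids <- integer(0)
  for (g in c("in", "out")) {
    cand <- which(correct & fit$inclusion == g)
    if (length(cand)) ids <- c(ids, min(cand) - 1L)
  }
  ids
}

#' Individual-level explanations for a fitted relevance model
#'
#' Runs the local surrogate explainer against the fitted population-level tree
#' (the black box is the tree's predicted probability of inclusion).
#'
#' @param fit a `relevance_fit`.
#' @param subject_ids 0-based subject ids to explain, or `"auto"`: one
#'   correctly-classified subject per in/out group (fewer when a group has no
#'   correctly classified subject).
#' @param config a [lime_config()].
#' @return List of `lime_explanation`s.
#' @export
explain_subjects <- function(fit, subject_ids = "auto",
                             config = lime_config()) {
  stopifnot(inherits(fit, "relevance_fit"))
  if (identical(subject_ids, "auto")) {
    subject_ids <- auto_explain_ids(fit)
  }
  summary <- lime_training_summary(fit$data, fit$covariates, config)
  black_box <- function(d) predict(fit$explainer, newdata = d, type = "prob")
  lapply(subject_ids, function(id) {
    explain_instance(black_box, fit$data[id + 1L, fit$covariates, drop = FALSE],
                     summary, config, subject_id = id)
  })
}
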