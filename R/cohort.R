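#' Declare a continuous covariate
#'
#' @param name column name.
#' @param lo,hi support bounds (`lo < hi`). Generated values are drawn from a
#'   normal distribution truncated to `[lo, hi]`.
#' @param mean,sd location and scale of the untruncated normal. Defaults:
#'   midpoint of the support and a quarter of its width.
#' @param integer round generated values to whole numbers (e.g. age in years).
#' @return A covariate specification used in [cohort_config()].
#' @export
cov_continuous <- function(name, lo, hi, mean = (lo + hi) / 2,
                           sd = (hi - lo) / 4, integer = FALSE) {
  if (!is.character(name) || length(name) != 1L || !nzchar(name)) {
    stop("covariate name must be a non-empty string", call. = FALSE)
  }
  if (!(lo < hi)) {
    stop(sprintf("covariate '%s': continuous support requires lo < hi", name),
         call. = FALSE)
  }
  if (sd <= 0) {
    stop(sprintf("covariate '%s': sd must be positive", name), call. = FALSE)
  }
  structure(list(name = name, kind = "continuous", lo = lo, hi = hi,
                 mean = mean, sd = sd, integer = isTRUE(integer)),
            class = "me_covariate")
}

#' Declare a categorical covariate
#'
#' @param name column name.
#' @param levels character vector of level names, in declared order; the first
#'   level is the default reference for dummy coding.
#' @param probs marginal probabilities, one per level, summing to 1.
#' @return A covariate specification used in [cohort_config()].
#' @export
cov_categorical <- function(name, levels, probs) {
  if (!is.character(name) || length(name) != 1L || !nzchar(name)) {
    stop("covariate name must be a non-empty string", call. = FALSE)
  }
  if (length(levels) < 2L || anyDuplicated(levels)) {
    stop(sprintf("covariate '%s': needs >= 2 distinct levels", name),
         call. = FALSE)
  }
  if (length(probs) != length(levels) || any(probs < 0)) {
    stop(sprintf("covariate '%s': one non-negative probability per level", name),
         call. = FALSE)
  }
  if (abs(sum(probs) - 1) > 1e-12) {
    stop(sprintf("covariate '%s': level probabilities must sum to 1 (got %.15g)",
                 name, sum(probs)), call. = FALSE)
  }
  structure(list(name = name, kind = "categorical",
                 levels = as.character(levels), probs = as.numeric(probs)),
            class = "me_covariate")
}

#' Configure a synthetic cohort generator
#'
#' Defines an NCDB-like registry cohort: independent covariates (truncated-
#' normal continuous, multinomial categorical) and a logistic treatment-
#' assignment model on the dummy-coded design.
#'
#' @param n subject count.
#' @param covariates ordered list of [cov_continuous()] / [cov_categorical()]
#'   specifications.
#' @param treatment_coefficients numeric vector on the log-odds scale:
#'   intercept first, then one coefficient per design column (continuous
#'   covariates contribute one column; a k-level categorical contributes k-1
#'   indicator columns, reference = first declared level, in declared order).
#' @param seed integer seed; [generate_cohort()] is deterministic given the
#'   config.
#' @return An object of class `cohort_config`.
#' @seealso [cohort_preset()] for shipped configurations.
#' @export
cohort_config <- function(n, covariates, treatment_coefficients, seed = 1L) {
  if (!is.numeric(n) || length(n) != 1L || n < 1 || n != round(n)) {
    stop("n must be a positive integer", call. = FALSE)
  }
  if (!length(covariates) ||
      !all(vapply(covariates, inherits, logical(1), "me_covariate"))) {
    stop("covariates must be a list of cov_continuous()/cov_categorical() specs",
         call. = FALSE)
  }
  nms <- vapply(covariates, `[[`, character(1), "name")
  if (anyDuplicated(nms)) {
    stop(sprintf("duplicated covariate name '%s'", nms[duplicated(nms)][1]),
         call. = FALSE)
  }
  p <- design_width(covariates)
  if (length(treatment_coefficients) != p + 1L) {
    stop(sprintf(paste0("treatment_coefficients: expected %d values ",
                        "(intercept + %d design columns), got %d"),
                 p + 1L, p, length(treatment_coefficients)), call. = FALSE)
  }
  names(covariates) <- nms
  structure(list(n = as.integer(n), covariates = covariates,
                 treatment_coefficients = as.numeric(treatment_coefficients),
                 seed = as.integer(seed)),
            class = "cohort_config")
}

design_width <- function(covariates) {
  sum(vapply(covariates, function(cv) {
    if (cv$kind == "continuous") 1L else length(cv$levels) - 1L
  }, integer(1)))
}

#' @export
print.cohort_config <- function(x, ...) {
  cat(sprintf("Synthetic cohort config: n = %d, seed = %d\n", x$n, x$seed))
  for (cv in x$covariates) {
    if (cv$kind == "continuous") {
      cat(sprintf("  %s: continuous on [%g, %g]%s (mean %g, sd %g)\n",
                  cv$name, cv$lo, cv$hi,
                  if (cv$integer) ", integer" else "", cv$mean, cv$sd))
    } else {
      cat(sprintf("  %s: categorical {%s}\n", cv$name,
                  paste(sprintf("%s %.3f", cv$levels, cv$probs), collapse = ", ")))
    }
  }
  invisible(x)
}

#' Load a shipped cohort preset
#'
#' Two presets emulate the printed marginals of published hospital-registry
#' cohorts: `"hn_ncdb"` (head-and-neck-like: n = 4042, age 71-90, site split
#' ~50.9/35.9/13.2, treated fraction targeting 0.63) and `"gbm_ncdb"`
#' (glioblastoma-like: adds surgery and year-of-diagnosis covariates; binary
#' treatment is the combined-modality vs radiation-alone comparison of the
#' three-arm design).
#'
#' @param name preset name.
#' @param n optional override of the preset subject count.
#' @param seed optional override of the preset seed.
#' @return A [cohort_config()].
#' @export
cohort_preset <- function(name = c("hn_ncdb", "gbm_ncdb"), n = NULL, seed = NULL) {
  name <- match.arg(name)
  path <- system.file("extdata", paste0(name, ".json"), package = "matchexplain",
                      mustWork = TRUE)
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  covs <- lapply(seq_len(nrow(cfg$covariates)), function(i) {
    cv <- cfg$covariates[i, ]
    if (cv$kind == "continuous") {
      cov_continuous(cv$name, cv$lo, cv$hi, cv$mean, cv$sd, isTRUE(cv$integer))
    } else {
      cov_categorical(cv$name, cv$levels[[1]], cv$probs[[1]])
    }
  })
  cohort_config(n %||% cfg$n, covs, cfg$treatment_coefficients,
                seed %||% cfg$seed)
}

rtruncnorm <- function(n, mean, sd, lo, hi) {
  plo <- stats::pnorm(lo, mean, sd)
  phi <- stats::pnorm(hi, mean, sd)
  stats::qnorm(stats::runif(n, plo, phi), mean, sd)
}

#' Generate a synthetic cohort
#'
#' Draws covariates independently per the schema, computes each subject's true
#' propensity score from the configured logistic treatment model, and draws
#' treatment `T ~ Bernoulli(true_score)`. Deterministic given the config
#' (covariates in schema order, then treatment).
#'
#' @param config a [cohort_config()].
#' @return A data.frame with columns `subject_id` (0-based), one column per
#'   covariate (categorical as factor with declared levels), `T` (0/1 integer)
#'   and `true_score`.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  with_seed(config$seed, {
    cols <- list(subject_id = seq_len(config$n) - 1L)
    for (cv in config$covariates) {
      if (cv$kind == "continuous") {
        x <- rtruncnorm(config$n, cv$mean, cv$sd, cv$lo, cv$hi)
        if (cv$integer) x <- as.integer(round(x))
        cols[[cv$name]] <- x
      } else {
        cols[[cv$name]] <- factor(
          sample(cv$levels, config$n, replace = TRUE, prob = cv$probs),
          levels = cv$levels)
      }
    }
    cohort <- as.data.frame(cols, stringsAsFactors = FALSE)
    score <- true_propensity(config, cohort)
    cohort$T <- as.integer(stats::rbinom(config$n, 1L, score))
    cohort$true_score <- score
    cohort
  })
}

#' True treatment-assignment propensity under a generator config
#'
#' Inverse-logit of `intercept + design %*% coefficients` where the design is
#' the dummy coding of [encode_design()] with reference = first declared level.
#'
#' @param config a [cohort_config()].
#' @param newdata data.frame of covariate rows conforming to the schema.
#' @return Numeric vector of probabilities in (0, 1).
#' @export
true_propensity <- function(config, newdata) {
  stopifnot(inherits(config, "cohort_config"))
  X <- encode_design(newdata, config$covariates)
  beta <- config$treatment_coefficients
  expit(drop(beta[1] + X %*% beta[-1]))
}

#' Dummy-code a cohort against a covariate schema
#'
#' Continuous covariates pass through; a k-level categorical yields k-1
#' indicator columns (reference level omitted). Column order is deterministic:
#' schema order, levels in declared order. Indicator columns are named
#' `<covariate><level>`.
#'
#' @param data data.frame containing the schema's covariate columns.
#' @param schema list of covariate specs (e.g. `config$covariates`).
#' @param reference_levels optional named character vector or list mapping a
#'   categorical covariate name to its reference level; defaults to the first
#'   declared level.
#' @return Numeric matrix with one row per subject and named columns.
#' @export
encode_design <- function(data, schema, reference_levels = NULL) {
  if (inherits(schema, "cohort_config")) schema <- schema$covariates
  cols <- list()
  for (cv in schema) {
    if (!cv$name %in% names(data)) {
      stop(sprintf("column '%s' missing from data", cv$name), call. = FALSE)
    }
    x <- data[[cv$name]]
    if (cv$kind == "continuous") {
      cols[[cv$name]] <- as.numeric(x)
    } else {
      ref <- reference_levels[[cv$name]] %||% cv$levels[1]
      if (!ref %in% cv$levels) {
        stop(sprintf("reference level '%s' absent from schema of '%s'",
                     ref, cv$name), call. = FALSE)
      }
      xc <- as.character(x)
      bad <- setdiff(unique(xc), cv$levels)
      if (length(bad)) {
        stop(sprintf("unknown level '%s' in covariate '%s'", bad[1], cv$name),
             call. = FALSE)
      }
      for (lev in setdiff(cv$levels, ref)) {
        cols[[paste0(cv$name, lev)]] <- as.numeric(xc == lev)
      }
    }
  }
  mat <- do.call(cbind, cols)
  rownames(mat) <- NULL
  mat
}

#' Write / read a cohort as CSV
#'
#' Columns `subject_id`, covariates in schema order, `T`; UTF-8, header row,
#' "." decimal separator. `true_score` is an in-memory column only and is not
#' written.
#'
#' @param cohort a cohort data.frame.
#' @param path file path.
#' @return `write_cohort()` returns `path` invisibly; `read_cohort()` returns
#'   the cohort data.frame (categorical columns as character).
#' @export
write_cohort <- function(cohort, path) {
  keep <- setdiff(names(cohort), "true_score")
  out <- cohort[keep]
  for (j in seq_along(out)) {
    if (is.factor(out[[j]])) out[[j]] <- as.character(out[[j]])
    out[[j]] <- fmt_machine(out[[j]])
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_cohort
#' @param categorical column names to coerce to factor on load (CSV carries no
#'   type information, so numerically coded categoricals — a comorbidity
#'   score, say — must be declared).
#' @export
read_cohort <- function(path, categorical = NULL) {
  ch <- utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  for (nm in categorical) {
    if (!nm %in% names(ch)) {
      stop(sprintf("categorical column '%s' missing from %s", nm, path),
           call. = FALSE)
    }
    ch[[nm]] <- factor(as.character(ch[[nm]]),
                       levels = sort(unique(as.character(ch[[nm]]))))
  }
  ch
}
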