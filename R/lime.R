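#' Configuration for local surrogate explanations
#'
#' @param n_permutations number of perturbed copies of the instance scored by
#'   the black box (>= 10; the first "perturbation" is the instance itself).
#' @param kernel_width positive width of the exponential similarity kernel, or
#'   `"default"` for `0.75 * sqrt(p)` with `p` the number of features.
#' @param n_features maximum number of features retained in the local model.
#' @param discretizer `"quartile"` (continuous covariates binned at the
#'   25/50/75th training percentiles) or `"none"` (standardized pass-through).
#' @param ridge optional ridge penalty for the weighted least-squares fits
#'   (default 0: ordinary WLS).
#' @param seed integer seed; explanations are deterministic given the config.
#' @return An object of class `lime_config`.
#' @export
lime_config <- function(n_permutations = 5000L, kernel_width = "default",
                        n_features = 5L, discretizer = c("quartile", "none"),
                        ridge = 0, seed = 1L) {
  discretizer <- match.arg(discretizer)
  if (n_permutations < 10L) stop("n_permutations must be >= 10", call. = FALSE)
  if (n_features < 1L) stop("n_features must be >= 1", call. = FALSE)
  if (is.numeric(kernel_width)) {
    if (kernel_width <= 0) stop("kernel_width must be > 0", call. = FALSE)
  } else if (!identical(kernel_width, "default")) {
    stop("kernel_width must be a positive number or \"default\"", call. = FALSE)
  }
  structure(list(n_permutations = as.integer(n_permutations),
                 kernel_width = kernel_width,
                 n_features = as.integer(n_features),
                 discretizer = discretizer, ridge = as.numeric(ridge),
                 seed = as.integer(seed)),
            class = "lime_config")
}

#' Quartile discretizer for a continuous training column
#'
#' Bin edges at the 25/50/75th percentiles (linear-interpolation quantiles);
#' a value maps to bin `1 + #(edges it exceeds)`, so values at or below the
#' first edge land in bin 1 and values above the last edge in bin 4. In
#' `"none"` mode values pass through z-scored by the training mean and sd.
#'
#' @param values numeric training column (>= 4 distinct values for quartile
#'   mode; non-constant in either mode).
#' @param mode `"quartile"` or `"none"`.
#' @return An object of class `lime_encoder` holding the edges (quartile) or
#'   mean/sd (none); apply it with [encode_bins()].
#' @export
discretize <- function(values, mode = c("quartile", "none")) {
  mode <- match.arg(mode)
  if (anyNA(values)) stop("missing values are not supported", call. = FALSE)
  if (mode == "quartile") {
    if (length(unique(values)) < 4L) {
      stop("quartile discretization needs >= 4 distinct values", call. = FALSE)
    }
    edges <- unname(stats::quantile(values, c(0.25, 0.5, 0.75), type = 7))
    structure(list(mode = "quartile", edges = edges), class = "lime_encoder")
  } else {
    s <- stats::sd(values)
    if (!is.finite(s) || s == 0) {
      stop("constant column cannot be standardized", call. = FALSE)
    }
    structure(list(mode = "none", mean = mean(values), sd = s),
              class = "lime_encoder")
  }
}

#' Apply a [discretize()] encoder
#'
#' @param encoder a `lime_encoder`.
#' @param values numeric vector.
#' @return Integer bins 1..4 (quartile mode) or z-scores (none mode).
#' @export
encode_bins <- function(encoder, values) {
  stopifnot(inherits(encoder, "lime_encoder"))
  if (encoder$mode == "quartile") {
    1L + rowSums(outer(values, encoder$edges, `>`))
  } else {
    (values - encoder$mean) / encoder$sd
  }
}

bin_label <- function(name, encoder, bin) {
  e <- signif(encoder$edges, 4)
  switch(bin,
         sprintf("%s <= %g", name, e[1]),
         sprintf("%g < %s <= %g", e[1], name, e[2]),
         sprintf("%g < %s <= %g", e[2], name, e[3]),
         sprintf("%g < %s", e[3], name))
}

#' Training summary feeding the local explainer
#'
#' Captures, per covariate, what the perturbation sampler needs: level
#' frequencies for categorical covariates; a quartile encoder plus the
#' training values (empirical sampling distribution) or a mean/sd
#' standardizer, for continuous ones.
#'
#' @param data training cohort data.frame.
#' @param covariates covariate columns; default: everything except treatment
#'   and bookkeeping columns.
#' @param config a [lime_config()] (sets the discretizer).
#' @return An object of class `lime_summary`.
#' @export
lime_training_summary <- function(data, covariates = NULL,
                                  config = lime_config()) {
  covariates <- covariates %||% default_covariates(data, "T")
  feats <- lapply(covariates, function(nm) {
    x <- data[[nm]]
    if (is.null(x)) stop(sprintf("column '%s' missing from data", nm),
                         call. = FALSE)
    if (is.numeric(x) &&
        (config$discretizer != "quartile" || length(unique(x)) >= 4L)) {
      enc <- discretize(as.numeric(x), config$discretizer)
      list(name = nm, kind = "continuous", encoder = enc,
           values = as.numeric(x))
    } else if (is.numeric(x)) {
      # too few distinct values to bin: treat as categorical
      lev <- as.character(sort(unique(x)))
      list(name = nm, kind = "categorical", levels = lev, numeric = TRUE,
           probs = as.numeric(table(factor(as.character(x), levels = lev))) /
             length(x))
    } else {
      xc <- as.character(x)
      lev <- if (is.factor(x)) levels(x) else sort(unique(xc))
      list(name = nm, kind = "categorical", levels = lev,
           probs = as.numeric(table(factor(xc, levels = lev))) / length(xc))
    }
  })
  names(feats) <- covariates
  structure(list(features = feats, discretizer = config$discretizer,
                 n_train = nrow(data)),
            class = "lime_summary")
}

#' Perturb one instance for local explanation
#'
#' Draws `n_permutations` rows: the first is the unperturbed instance; in the
#' others every covariate is independently resampled from its training
#' marginal (empirical values for continuous covariates, level frequencies for
#' categorical ones). The interpretable design has one column per covariate:
#' an indicator that the perturbed entry falls in the instance's own
#' bin/level, or the z-scored value when the discretizer is `"none"`.
#' Distances are Euclidean distances from each design row to the instance's
#' row, scaled by `sqrt(p)`.
#'
#' @param instance single-row data.frame conforming to the training schema.
#' @param summary a [lime_training_summary()].
#' @param config a [lime_config()].
#' @return List with `data` (raw perturbed rows), `design` (numeric matrix,
#'   named columns), and `distances`.
#' @export
perturb <- function(instance, summary, config = lime_config()) {
  stopifnot(inherits(summary, "lime_summary"), nrow(instance) == 1L)
  n <- config$n_permutations
  p <- length(summary$features)
  raw <- vector("list", p)
  design <- matrix(0, n, p)
  colnames(design) <- vapply(summary$features, `[[`, character(1), "name")
  feat_names <- character(p)
  with_seed(config$seed, {
    for (j in seq_len(p)) {
      ft <- summary$features[[j]]
      if (ft$kind == "categorical") {
        x0 <- as.character(instance[[ft$name]])
        if (!x0 %in% ft$levels) {
          stop(sprintf("unknown level '%s' in covariate '%s'", x0, ft$name),
               call. = FALSE)
        }
        draws <- sample(ft$levels, n, replace = TRUE, prob = ft$probs)
        draws[1] <- x0
        raw[[j]] <- if (isTRUE(ft$numeric)) {
          as.numeric(draws)
        } else {
          factor(draws, levels = ft$levels)
        }
        design[, j] <- as.numeric(draws == x0)
        feat_names[j] <- sprintf("%s = %s", ft$name, x0)
      } else {
        x0 <- as.numeric(instance[[ft$name]])
        if (ft$encoder$mode == "quartile") {
          draws <- sample(ft$values, n, replace = TRUE)
          draws[1] <- x0
          b0 <- encode_bins(ft$encoder, x0)
          design[, j] <- as.numeric(encode_bins(ft$encoder, draws) == b0)
          feat_names[j] <- bin_label(ft$name, ft$encoder, b0)
        } else {
          draws <- stats::rnorm(n, ft$encoder$mean, ft$encoder$sd)
          draws[1] <- x0
          design[, j] <- encode_bins(ft$encoder, draws)
          feat_names[j] <- ft$name
        }
        raw[[j]] <- draws
      }
    }
  })
  names(raw) <- colnames(design)
  data <- as.data.frame(raw, stringsAsFactors = FALSE, check.names = FALSE)
  delta <- sweep(design, 2, design[1, ])
  distances <- sqrt(rowSums(delta^2)) / sqrt(p)
  list(data = data, design = design, distances = distances,
       feature_names = feat_names)
}

#' Exponential similarity kernel
#'
#' `exp(-d^2 / width^2)`.
#'
#' @param distances non-negative distances.
#' @param width positive kernel width.
#' @return Weights in (0, 1\].
#' @export
kernel_similarity <- function(distances, width) {
  if (any(distances < 0)) stop("distances must be >= 0", call. = FALSE)
  if (width <= 0) stop("width must be > 0", call. = FALSE)
  exp(-distances^2 / width^2)
}

# weighted least squares with optional ridge penalty; NA coefficients
# (rank deficiency) are treated as 0
wls_fit <- function(Z, y, w, ridge = 0) {
  X <- cbind("(Intercept)" = 1, Z)
  if (ridge > 0) {
    XtW <- t(X * w)
    pen <- diag(c(0, rep(ridge, ncol(Z))))
    beta <- solve(XtW %*% X + pen, XtW %*% y)
    beta <- drop(beta)
    names(beta) <- colnames(X)
  } else {
    fit <- stats::lm.wfit(X, y, w)
    beta <- fit$coefficients
    beta[is.na(beta)] <- 0
  }
  beta
}

#' Explain one subject's classification with a local linear surrogate
#'
#' Perturbs the instance, scores the perturbations with the black box, weights
#' them by similarity to the instance, selects the `n_features` columns with
#' the largest absolute coefficients of a full weighted least-squares fit, and
#' refits on the kept columns. The explanation fit is the weighted R-squared
#' of that final local model.
#'
#' @param black_box function mapping a data.frame of covariate rows to the
#'   probability of the positive ("in") class.
#' @param instance single-row data.frame.
#' @param summary a [lime_training_summary()].
#' @param config a [lime_config()].
#' @param subject_id optional subject id recorded in the explanation.
#' @param labels class labels as `c(negative, positive)`.
#' @return An object of class `lime_explanation`: `subject_id`,
#'   `predicted_label`, `predicted_prob`, `features` (data.frame of feature,
#'   weight, direction), `intercept`, `explanation_fit`.
#' @export
explain_instance <- function(black_box, instance, summary,
                             config = lime_config(), subject_id = NA_integer_,
                             labels = c("out", "in")) {
  pert <- perturb(instance, summary, config)
  y <- tryCatch(as.numeric(black_box(pert$data)), error = function(e) NULL)
  keep_rows <- seq_len(nrow(pert$data))
  if (is.null(y) || length(y) != nrow(pert$data)) {
    # row-wise fallback: drop rows the black box cannot score
    y <- vapply(seq_len(nrow(pert$data)), function(i) {
      tryCatch(as.numeric(black_box(pert$data[i, , drop = FALSE])),
               error = function(e) NA_real_)
    }, numeric(1))
    keep_rows <- which(!is.na(y))
    dropped <- nrow(pert$data) - length(keep_rows)
    if (dropped > 0) {
      if (dropped > nrow(pert$data) / 2) {
        stop("black box failed on more than half of the perturbed rows",
             call. = FALSE)
      }
      warning(sprintf("black box failed on %d perturbed row(s); dropped",
                      dropped), call. = FALSE)
      y <- y[keep_rows]
    }
  }
  Z <- pert$design[keep_rows, , drop = FALSE]
  p <- ncol(Z)
  width <- if (identical(config$kernel_width, "default")) {
    0.75 * sqrt(p)
  } else {
    config$kernel_width
  }
  w <- kernel_similarity(pert$distances[keep_rows], width)
  prob0 <- as.numeric(black_box(instance))
  pred_label <- if (prob0 >= 0.5) labels[2] else labels[1]

  ybar <- stats::weighted.mean(y, w)
  tss <- sum(w * (y - ybar)^2)
  if (tss < 1e-12) {
    # zero-variance response: all weights 0, explanation fit defined as 0
    k <- seq_len(min(config$n_features, p))
    feats <- data.frame(feature = pert$feature_names[k],
                        column = colnames(Z)[k],
                        weight = rep(0, length(k)),
                        direction = rep("supports", length(k)),
                        stringsAsFactors = FALSE)
    return(structure(list(subject_id = subject_id,
                          predicted_label = pred_label,
                          predicted_prob = prob0, features = feats,
                          intercept = ybar, explanation_fit = 0,
                          kernel_width = width, labels = labels),
                     class = "lime_explanation"))
  }
  beta_full <- wls_fit(Z, y, w, config$ridge)[-1]
  ord <- order(-abs(beta_full), seq_along(beta_full))
  keep <- sort(ord[seq_len(min(config$n_features, p))])
  beta <- wls_fit(Z[, keep, drop = FALSE], y, w, config$ridge)
  intercept <- beta[1]
  wts <- beta[-1]
  yhat <- intercept + drop(Z[, keep, drop = FALSE] %*% wts)
  rss <- sum(w * (y - yhat)^2)
  fit_r2 <- max(0, min(1, 1 - rss / tss))
  # a positive weight pushes the in-probability up: it supports an "in"
  # prediction and contradicts an "out" one
  direction <- ifelse((wts > 0) == (pred_label == labels[2]),
                      "supports", "contradicts")
  direction[wts == 0] <- "supports"
  feats <- data.frame(feature = pert$feature_names[keep],
                      column = colnames(Z)[keep],
                      weight = unname(wts),
                      direction = unname(direction),
                      stringsAsFactors = FALSE)
  feats <- feats[order(-abs(feats$weight)), ]
  rownames(feats) <- NULL
  structure(list(subject_id = subject_id, predicted_label = pred_label,
                 predicted_prob = prob0, features = feats,
                 intercept = unname(intercept), explanation_fit = fit_r2,
                 kernel_width = width, labels = labels),
            class = "lime_explanation")
}

#' @export
print.lime_explanation <- function(x, ...) {
  cat(sprintf("Local explanation for subject %s: predicted '%s' (p = %.3f), fit R^2 = %.3f\n",
              format(x$subject_id), x$predicted_label, x$predicted_prob,
              x$explanation_fit))
  for (i in seq_len(nrow(x$features))) {
    cat(sprintf("  %-28s %+.4f  (%s)\n", x$features$feature[i],
                x$features$weight[i], x$features$direction[i]))
  }
  invisible(x)
}

#' Group summary of explanation quality
#'
#' Per inclusion group, the mean explanation fit and the mean absolute
#' top-feature weight over the supplied explanations.
#'
#' @param explanations list of [explain_instance()] results.
#' @param inclusion factor of inclusion labels for the whole cohort (position
#'   `i` = subject id `i - 1`).
#' @return data.frame with one row per group (`out`, `in`): `n`, `mean_fit`,
#'   `mean_top_weight` (NA when a group has no explanations).
#' @export
summarize_explanations <- function(explanations, inclusion) {
  ids <- vapply(explanations, `[[`, numeric(1), "subject_id")
  if (anyNA(ids)) stop("explanations must carry subject_id", call. = FALSE)
  grp <- as.character(inclusion)[ids + 1L]
  fits <- vapply(explanations, `[[`, numeric(1), "explanation_fit")
  topw <- vapply(explanations, function(e) {
    if (nrow(e$features)) max(abs(e$features$weight)) else 0
  }, numeric(1))
  out <- lapply(c("out", "in"), function(g) {
    sel <- grp == g
    data.frame(group = g, n = sum(sel),
               mean_fit = if (any(sel)) mean(fits[sel]) else NA_real_,
               mean_top_weight = if (any(sel)) mean(topw[sel]) else NA_real_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Serialize explanations to JSON
#'
#' @param explanations list of `lime_explanation`s.
#' @param path optional output file.
#' @return JSON string (invisibly when written).
#' @export
explanations_to_json <- function(explanations, path = NULL) {
  obj <- lapply(explanations, function(e) {
    list(subject_id = e$subject_id, predicted_label = e$predicted_label,
         predicted_prob = e$predicted_prob,
         features = e$features[c("feature", "weight", "direction")],
         intercept = e$intercept, explanation_fit = e$explanation_fit)
  })
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         dataframe = "rows")
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}
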