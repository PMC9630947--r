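#' Population-level explainer of match inclusion
#'
#' Fits a classification tree for the probability that a subject is "in" the
#' matched sample given its covariates, then prunes it at the complexity
#' parameter minimizing the cross-validated misclassification error. If the
#' inclusion labels are single-class the root stump is returned with a
#' degeneracy flag instead of an error.
#'
#' @param data cohort data.frame.
#' @param inclusion factor with levels `c("out", "in")` (e.g. from
#'   [label_inclusion()]).
#' @param covariates covariate columns; default: everything except treatment
#'   and bookkeeping columns.
#' @param control a [tree_control()] (its seed fixes the CV folds).
#' @return A `cart_tree` with attributes `cp` (selected complexity), `cv`
#'   (the `cv_curve`) and `degenerate` (single-class flag).
#' @export
fit_population_explainer <- function(data, inclusion, covariates = NULL,
                                     control = tree_control()) {
  covariates <- covariates %||% default_covariates(data, "T")
  inclusion <- factor(as.character(inclusion), levels = c("out", "in"))
  if (anyNA(inclusion)) stop("inclusion labels must be 'in'/'out'", call. = FALSE)
  X <- data[covariates]
  if (length(unique(inclusion)) < 2L) {
    tree <- grow_tree(X, inclusion,
                      tree_control(minsplit = control$minsplit,
                                   minbucket = control$minbucket,
                                   cp_grow = control$cp_grow, maxdepth = 0L,
                                   n_folds = control$n_folds,
                                   seed = control$seed))
    attr(tree, "cp") <- NA_real_
    attr(tree, "cv") <- NULL
    attr(tree, "degenerate") <- TRUE
    return(tree)
  }
  cv <- cross_validated_error(X, inclusion, control)
  cp <- select_cp(cv, "min")
  tree <- prune_tree(attr(cv, "tree"), cp)
  attr(tree, "cp") <- cp
  attr(tree, "cv") <- cv
  attr(tree, "degenerate") <- FALSE
  tree
}

#' Characteristics-by-match-status balance table
#'
#' Summarizes every covariate by inclusion group: continuous covariates as
#' mean (sd) with a Welch two-sample t-test p-value; categorical covariates as
#' level counts and column percentages with a Pearson chi-square p-value
#' (no continuity correction, df = levels - 1). Levels absent from both groups
#' are dropped from the test with a note.
#'
#' @param data cohort data.frame.
#' @param inclusion factor with levels `c("out", "in")`.
#' @param covariates covariate columns to summarize.
#' @return An object of class `balance_table`.
#' @export
characteristics_table <- function(data, inclusion, covariates = NULL) {
  covariates <- covariates %||% default_covariates(data, "T")
  inclusion <- factor(as.character(inclusion), levels = c("out", "in"))
  n_in <- sum(inclusion == "in")
  n_out <- sum(inclusion == "out")
  if (n_in == 0L || n_out == 0L) {
    stop("both inclusion groups must be non-empty", call. = FALSE)
  }
  rows <- lapply(covariates, function(nm) {
    x <- data[[nm]]
    if (is.numeric(x)) {
      xi <- x[inclusion == "in"]; xo <- x[inclusion == "out"]
      p <- welch_p(xi, xo)
      list(covariate = nm, type = "continuous",
           mean_in = mean(xi), sd_in = stats::sd(xi),
           mean_out = mean(xo), sd_out = stats::sd(xo),
           p_value = p)
    } else {
      xc <- factor(as.character(x),
                   levels = if (is.factor(x)) levels(x) else sort(unique(as.character(x))))
      tab <- table(xc, inclusion)
      dropped <- rownames(tab)[rowSums(tab) == 0L]
      tab <- tab[rowSums(tab) > 0L, , drop = FALSE]
      p <- if (nrow(tab) >= 2L) {
        suppressWarnings(stats::chisq.test(tab, correct = FALSE)$p.value)
      } else {
        NA_real_
      }
      list(covariate = nm, type = "categorical",
           levels = rownames(tab),
           count_in = unname(tab[, "in"]), count_out = unname(tab[, "out"]),
           pct_in = unname(100 * tab[, "in"] / n_in),
           pct_out = unname(100 * tab[, "out"] / n_out),
           dropped_levels = dropped, p_value = p)
    }
  })
  structure(list(covariates = rows, n_in = n_in, n_out = n_out),
            class = "balance_table")
}

# Welch two-sample t-test p-value; degenerate zero-variance comparisons give
# p = 1 when the group means coincide (identical samples) and p ~ 0 otherwise.
welch_p <- function(a, b) {
  if (length(a) < 2L || length(b) < 2L) return(NA_real_)
  if (stats::sd(a) == 0 && stats::sd(b) == 0) {
    return(if (mean(a) == mean(b)) 1 else 0)
  }
  stats::t.test(a, b)$p.value
}

#' @export
print.balance_table <- function(x, ...) {
  cat(sprintf("Characteristics by match status: n_out = %d, n_in = %d\n",
              x$n_out, x$n_in))
  fmt_p <- function(p) {
    if (is.na(p)) "-" else if (p < 0.001) "< .001" else sprintf("%.3f", p)
  }
  for (cv in x$covariates) {
    if (cv$type == "continuous") {
      cat(sprintf("  %-22s %8s %8s   p %s\n", cv$covariate,
                  sprintf("%.0f (%.0f)", cv$mean_out, cv$sd_out),
                  sprintf("%.0f (%.0f)", cv$mean_in, cv$sd_in),
                  fmt_p(cv$p_value)))
    } else {
      cat(sprintf("  %-22s %8s %8s   p %s\n", cv$covariate, "out", "in",
                  fmt_p(cv$p_value)))
      for (i in seq_along(cv$levels)) {
        cat(sprintf("    %-20s %9s %9s\n", cv$levels[i],
                    sprintf("%d (%.1f)", cv$count_out[i], cv$pct_out[i]),
                    sprintf("%d (%.1f)", cv$count_in[i], cv$pct_in[i])))
      }
    }
  }
  invisible(x)
}

#' Write a balance table as CSV and/or JSON
#'
#' The CSV mirrors the one-block-per-covariate report layout (rounded values);
#' the JSON carries full machine precision.
#'
#' @param table a `balance_table`.
#' @param csv_path,json_path output paths (`NULL` to skip).
#' @return Invisibly, the table.
#' @export
write_balance_table <- function(table, csv_path = NULL, json_path = NULL) {
  if (!is.null(csv_path)) {
    rows <- list(data.frame(covariate = "n", level = "",
                            out = as.character(table$n_out),
                            "in" = as.character(table$n_in),
                            p_value = "", check.names = FALSE))
    for (cv in table$covariates) {
      pv <- ifelse(is.na(cv$p_value), "", sprintf("%.4f", cv$p_value))
      if (cv$type == "continuous") {
        rows <- c(rows, list(data.frame(
          covariate = cv$covariate, level = "",
          out = sprintf("%.1f (%.1f)", cv$mean_out, cv$sd_out),
          "in" = sprintf("%.1f (%.1f)", cv$mean_in, cv$sd_in),
          p_value = pv, check.names = FALSE)))
      } else {
        rows <- c(rows, list(data.frame(
          covariate = cv$covariate, level = cv$levels,
          out = sprintf("%d (%.1f)", cv$count_out, cv$pct_out),
          "in" = sprintf("%d (%.1f)", cv$count_in, cv$pct_in),
          p_value = c(pv, rep("", length(cv$levels) - 1L)),
          check.names = FALSE)))
      }
    }
    utils::write.csv(do.call(rbind, rows), csv_path, row.names = FALSE)
  }
  if (!is.null(json_path)) {
    jsonlite::write_json(unclass(table), json_path, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  }
  invisible(table)
}
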