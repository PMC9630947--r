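#' Control parameters for the classification-tree engine
#'
#' Defaults mirror the conventional recursive-partitioning settings: a node is
#' split only if it holds at least `minsplit` subjects, children must hold at
#' least `minbucket`, and a split must reduce total Gini impurity by at least
#' `cp_grow` of the root's impurity.
#'
#' @param minsplit minimum node size to attempt a split (>= 2 * minbucket).
#' @param minbucket minimum leaf size (>= 1).
#' @param cp_grow complexity threshold during growth, on the relative
#'   impurity-decrease scale.
#' @param maxdepth depth cap (root has depth 0; `maxdepth = 0` forces a
#'   root-only tree).
#' @param n_folds cross-validation fold count (>= 2).
#' @param seed integer seed for fold assignment (and any per-split feature
#'   subsampling).
#' @return An object of class `tree_control`.
#' @export
tree_control <- function(minsplit = 20L, minbucket = 7L, cp_grow = 0.01,
                         maxdepth = 30L, n_folds = 10L, seed = 1L) {
  if (minbucket < 1L) stop("minbucket must be >= 1", call. = FALSE)
  if (minsplit < 2L * minbucket) {
    stop("minsplit must be >= 2 * minbucket", call. = FALSE)
  }
  if (n_folds < 2L) stop("n_folds must be >= 2", call. = FALSE)
  if (cp_grow < 0) stop("cp_grow must be >= 0", call. = FALSE)
  if (maxdepth < 0L) stop("maxdepth must be >= 0", call. = FALSE)
  structure(list(minsplit = as.integer(minsplit),
                 minbucket = as.integer(minbucket),
                 cp_grow = as.numeric(cp_grow),
                 maxdepth = as.integer(maxdepth),
                 n_folds = as.integer(n_folds),
                 seed = as.integer(seed)),
            class = "tree_control")
}

#' Gini impurity of a binary node
#'
#' `1 - p^2 - (1 - p)^2` with `p = n_pos / (n_pos + n_neg)`.
#'
#' @param n_pos,n_neg class counts (non-negative, not both zero). `n_pos` may
#'   also be a length-2 vector of both counts.
#' @return Impurity in \[0, 0.5\].
#' @export
gini_impurity <- function(n_pos, n_neg = NULL) {
  if (is.null(n_neg)) {
    if (length(n_pos) != 2L) stop("supply two counts", call. = FALSE)
    n_neg <- n_pos[2]; n_pos <- n_pos[1]
  }
  if (n_pos < 0 || n_neg < 0 || n_pos + n_neg == 0) {
    stop("counts must be non-negative and not both zero", call. = FALSE)
  }
  p <- n_pos / (n_pos + n_neg)
  1 - p^2 - (1 - p)^2
}

# --- internal data preparation ------------------------------------------

# y -> list(y01 integer 0/1 (1 = positive class), levels = c(neg, pos))
as_binary_y <- function(y) {
  if (is.factor(y)) {
    lev <- levels(y)
    if (length(lev) != 2L) stop("y must have exactly 2 levels", call. = FALSE)
    list(y01 = as.integer(y) - 1L, levels = lev)
  } else if (is.logical(y)) {
    list(y01 = as.integer(y), levels = c("FALSE", "TRUE"))
  } else if (is.numeric(y) && all(y %in% c(0, 1))) {
    list(y01 = as.integer(y), levels = c("0", "1"))
  } else if (is.character(y)) {
    as_binary_y(factor(y, levels = sort(unique(y))))
  } else {
    stop("y must be a 2-level factor, logical, 0/1 numeric or character",
         call. = FALSE)
  }
}

# X data.frame -> per-column list(type, x numeric | integer codes, levels)
prep_x <- function(X) {
  stopifnot(is.data.frame(X), ncol(X) >= 1L)
  if (anyNA(X)) stop("missing values are not supported", call. = FALSE)
  lapply(X, function(col) {
    if (is.numeric(col)) {
      list(type = "continuous", x = as.numeric(col), levels = NULL)
    } else {
      f <- if (is.factor(col)) col else factor(col, levels = sort(unique(col)))
      list(type = "categorical", x = as.integer(f), levels = levels(f))
    }
  })
}

# --- split search --------------------------------------------------------

# Exhaustive best split over covariates `vars` for the rows `idx`.
# Returns NULL or list(var, type, threshold | levels_left, decrease) where
# decrease is the total (count-weighted) Gini decrease n*g(node) - sum n_c*g_c.
# Ties: earlier covariate wins; within a continuous covariate, the smaller
# cutpoint; within a categorical one, the first bipartition in enumeration
# order (level subsets ordered by binary mask over declared levels).
node_best_split <- function(cols, y01, idx, minbucket, vars = seq_along(cols)) {
  n <- length(idx)
  yk <- y01[idx]
  npos <- sum(yk)
  if (npos == 0L || npos == n || n < 2L * minbucket) return(NULL)
  g_node <- gini_impurity(npos, n - npos)
  node_imp <- n * g_node
  best <- NULL
  gini_sum <- function(nl, pl) {
    # total impurity of a child set: nl*g = nl - (pl^2 + (nl-pl)^2)/nl
    nl - (pl^2 + (nl - pl)^2) / nl
  }
  for (j in vars) {
    cl <- cols[[j]]
    if (cl$type == "continuous") {
      x <- cl$x[idx]
      o <- order(x)
      xs <- x[o]; ys <- yk[o]
      cut_ok <- which(xs[-n] < xs[-1])
      cut_ok <- cut_ok[cut_ok >= minbucket & cut_ok <= n - minbucket]
      if (!length(cut_ok)) next
      cp_pos <- cumsum(ys)
      nl <- cut_ok
      pl <- cp_pos[cut_ok]
      dec <- node_imp - (gini_sum(nl, pl) + gini_sum(n - nl, npos - pl))
      k <- which.max(dec)
      if (is.null(best) || dec[k] > best$decrease + 1e-12) {
        i <- cut_ok[k]
        best <- list(var = j, type = "continuous",
                     threshold = (xs[i] + xs[i + 1]) / 2,
                     decrease = dec[k])
      }
    } else {
      x <- cl$x[idx]
      k_all <- length(cl$levels)
      tab_n <- tabulate(x, nbins = k_all)
      tab_p <- vapply(seq_len(k_all),
                      function(l) sum(yk[x == l]), numeric(1))
      present <- which(tab_n > 0L)
      kp <- length(present)
      if (kp < 2L) next
      if (kp <= 12L) {
        # exhaustive bipartitions: first present level pinned to the left side
        m <- kp - 1L
        masks <- 0:(2^m - 2L)          # exclude all-left
        memb <- matrix(0, length(masks), kp)
        memb[, 1] <- 1
        for (b in seq_len(m)) {
          memb[, b + 1L] <- bitwAnd(masks, bitwShiftL(1L, b - 1L)) > 0L
        }
      } else {
        # order present levels by positive-class proportion; prefixes are
        # optimal for a binary outcome
        ord <- order(tab_p[present] / tab_n[present], present)
        present <- present[ord]
        memb <- matrix(0, kp - 1L, kp)
        for (i in seq_len(kp - 1L)) memb[i, seq_len(i)] <- 1
      }
      nl <- drop(memb %*% tab_n[present])
      pl <- drop(memb %*% tab_p[present])
      ok <- nl >= minbucket & (n - nl) >= minbucket
      if (!any(ok)) next
      dec <- rep(-Inf, length(nl))
      dec[ok] <- node_imp -
        (gini_sum(nl[ok], pl[ok]) + gini_sum(n - nl[ok], npos - pl[ok]))
      k <- which.max(dec)
      if (dec[k] > -Inf && (is.null(best) || dec[k] > best$decrease + 1e-12)) {
        best <- list(var = j, type = "categorical",
                     levels_left = cl$levels[present[memb[k, ] > 0]],
                     decrease = dec[k])
      }
    }
  }
  best
}

#' Best single split of a node
#'
#' Exhaustive search for the (covariate, cutpoint or level-bipartition)
#' maximizing the count-weighted Gini impurity decrease, subject to the
#' `minbucket` constraint. Returns `NULL` when no admissible split attains a
#' relative improvement (decrease divided by the node's total impurity) of at
#' least `control$cp_grow`. Continuous cutpoints sit at midpoints between
#' adjacent observed values; categorical bipartitions are searched exhaustively
#' for up to 12 observed levels and by the class-proportion ordering (exact for
#' a binary outcome) above that.
#'
#' @param X data.frame of covariates (numeric or factor/character columns).
#' @param y binary outcome (2-level factor, logical, or 0/1).
#' @param control a [tree_control()].
#' @return `NULL`, or a list with `var` (column name), `type`, `threshold`
#'   (continuous; left child is `x < threshold`) or `levels_left`
#'   (categorical), `decrease` (total Gini decrease) and `improvement`
#'   (relative to the node's impurity).
#' @export
best_split <- function(X, y, control = tree_control()) {
  cols <- prep_x(X)
  yb <- as_binary_y(y)
  n <- nrow(X)
  if (n < control$minsplit) return(NULL)
  npos <- sum(yb$y01)
  if (npos == 0L || npos == n) return(NULL)
  node_imp <- n * gini_impurity(npos, n - npos)
  sp <- node_best_split(cols, yb$y01, seq_len(n), control$minbucket)
  if (is.null(sp)) return(NULL)
  sp$improvement <- sp$decrease / node_imp
  if (sp$improvement < control$cp_grow - 1e-12) return(NULL)
  sp$var <- names(X)[sp$var]
  sp
}

# --- growing -------------------------------------------------------------

new_node <- function(id, parent, depth, n, n_pos, pos_level, neg_level) {
  prob <- n_pos / n
  list(id = id, parent = parent, depth = depth, is_leaf = TRUE,
       n = n, n_pos = n_pos, n_neg = n - n_pos, prob = prob,
       label = if (n_pos >= n - n_pos) pos_level else neg_level,
       split = NULL, children = NULL)
}

#' Grow a binary classification tree
#'
#' Recursive partitioning with the Gini criterion: nodes of at least
#' `minsplit` subjects and depth below `maxdepth` are split by [best_split()]
#' until no admissible split improves impurity by at least `cp_grow` of the
#' root impurity. Leaves carry class counts, the positive-class probability
#' and the majority label (ties go to the positive class).
#'
#' @param X data.frame of covariates.
#' @param y binary outcome; the second factor level (or 1) is the positive
#'   class whose probability the tree reports.
#' @param control a [tree_control()].
#' @param mtry optional number of covariates sampled (without replacement,
#'   from the current RNG stream) as split candidates at each node; `NULL`
#'   considers all covariates.
#' @return An object of class `cart_tree`.
#' @export
grow_tree <- function(X, y, control = tree_control(), mtry = NULL) {
  cols <- prep_x(X)
  yb <- as_binary_y(y)
  n <- nrow(X)
  if (length(yb$y01) != n) stop("length(y) must equal nrow(X)", call. = FALSE)
  if (n < control$minbucket) {
    stop(sprintf("need at least minbucket = %d rows, got %d",
                 control$minbucket, n), call. = FALSE)
  }
  if (!is.null(mtry)) {
    mtry <- as.integer(mtry)
    if (mtry < 1L || mtry > length(cols)) {
      stop("mtry must be between 1 and the number of covariates", call. = FALSE)
    }
  }
  root_imp <- n * gini_impurity(sum(yb$y01), n - sum(yb$y01))
  env <- new.env(parent = emptyenv())
  env$nodes <- list()
  env$next_id <- 1L

  build <- function(idx, depth, parent) {
    id <- env$next_id
    env$next_id <- id + 1L
    npos <- sum(yb$y01[idx])
    node <- new_node(id, parent, depth, length(idx), npos,
                     yb$levels[2], yb$levels[1])
    env$nodes[[id]] <- node
    sp <- NULL
    if (length(idx) >= control$minsplit && depth < control$maxdepth &&
        root_imp > 0) {
      vars <- seq_along(cols)
      if (!is.null(mtry) && mtry < length(cols)) {
        vars <- sort(sample(vars, mtry))
      }
      sp <- node_best_split(cols, yb$y01, idx, control$minbucket, vars)
      if (!is.null(sp) && sp$decrease < control$cp_grow * root_imp - 1e-12) {
        sp <- NULL
      }
    }
    if (!is.null(sp)) {
      cl <- cols[[sp$var]]
      go_left <- if (sp$type == "continuous") {
        cl$x[idx] < sp$threshold
      } else {
        cl$levels[cl$x[idx]] %in% sp$levels_left
      }
      sp_out <- list(var = names(cols)[sp$var], type = sp$type,
                     threshold = sp$threshold, levels_left = sp$levels_left,
                     decrease = sp$decrease,
                     improvement = sp$decrease / root_imp)
      left <- build(idx[go_left], depth + 1L, id)
      right <- build(idx[!go_left], depth + 1L, id)
      node$is_leaf <- FALSE
      node$split <- sp_out
      node$children <- c(left, right)
      env$nodes[[id]] <- node
    }
    id
  }
  build(seq_len(n), 0L, 0L)

  structure(list(nodes = env$nodes,
                 y_levels = yb$levels,
                 n = n,
                 var_names = names(cols),
                 var_types = vapply(cols, `[[`, character(1), "type"),
                 var_levels = lapply(cols, `[[`, "levels"),
                 control = control),
            class = "cart_tree")
}

n_leaves <- function(tree) sum(vapply(tree$nodes, `[[`, logical(1), "is_leaf"))

n_nodes <- function(tree) length(tree$nodes)

# training misclassification risk of the whole tree (fraction of tree$n)
tree_risk <- function(tree) {
  sum(vapply(tree$nodes, function(nd) {
    if (nd$is_leaf) min(nd$n_pos, nd$n_neg) else 0
  }, numeric(1))) / tree$n
}

#' @export
print.cart_tree <- function(x, ...) {
  cat(sprintf("Classification tree: %d nodes (%d leaves), n = %d, classes %s/%s\n",
              n_nodes(x), n_leaves(x), x$n, x$y_levels[1], x$y_levels[2]))
  recurse <- function(id, indent) {
    nd <- x$nodes[[id]]
    pad <- strrep("  ", indent)
    desc <- if (nd$is_leaf) "leaf" else split_text(nd$split)
    cat(sprintf("%s[%d] %s  n=%d  P(%s)=%.3f  -> %s\n", pad, id, desc, nd$n,
                x$y_levels[2], nd$prob, nd$label))
    if (!nd$is_leaf) {
      recurse(nd$children[1], indent + 1L)
      recurse(nd$children[2], indent + 1L)
    }
  }
  recurse(1L, 0L)
  invisible(x)
}

split_text <- function(sp) {
  if (sp$type == "continuous") {
    sprintf("%s < %g", sp$var, sp$threshold)
  } else {
    sprintf("%s in {%s}", sp$var, paste(sp$levels_left, collapse = ","))
  }
}

# --- prediction ----------------------------------------------------------

#' Predict from a classification tree
#'
#' Routes each row from the root to a terminal node and returns the leaf's
#' positive-class probability and/or majority label. A categorical level not
#' seen in training is routed to the larger child and flagged in the
#' `"unseen_routed"` attribute.
#'
#' @param object a `cart_tree`.
#' @param newdata data.frame containing the training covariate columns.
#' @param type `"prob"` (positive-class probability), `"label"`, or `"both"`
#'   (data.frame of node id, probability, label).
#' @param ... unused.
#' @return Per `type`; with attribute `unseen_routed` (logical per row).
#' @export
predict.cart_tree <- function(object, newdata, type = c("prob", "label", "both"),
                              ...) {
  type <- match.arg(type)
  missing_cols <- setdiff(object$var_names, names(newdata))
  if (length(missing_cols)) {
    stop(sprintf("newdata lacks column '%s'", missing_cols[1]), call. = FALSE)
  }
  n <- nrow(newdata)
  leaf_id <- integer(n)
  unseen <- logical(n)
  route <- function(id, idx) {
    if (!length(idx)) return(invisible())
    nd <- object$nodes[[id]]
    if (nd$is_leaf) {
      leaf_id[idx] <<- id
      return(invisible())
    }
    sp <- nd$split
    x <- newdata[[sp$var]][idx]
    if (sp$type == "continuous") {
      go_left <- as.numeric(x) < sp$threshold
    } else {
      xc <- as.character(x)
      known <- xc %in% object$var_levels[[sp$var]]
      go_left <- xc %in% sp$levels_left
      if (any(!known)) {
        kids <- object$nodes[nd$children]
        major_left <- kids[[1]]$n >= kids[[2]]$n
        go_left[!known] <- major_left
        unseen[idx[!known]] <<- TRUE
      }
    }
    route(nd$children[1], idx[go_left])
    route(nd$children[2], idx[!go_left])
  }
  route(1L, seq_len(n))
  prob <- vapply(leaf_id, function(id) object$nodes[[id]]$prob, numeric(1))
  label <- vapply(leaf_id, function(id) object$nodes[[id]]$label, character(1))
  out <- switch(type,
                prob = prob,
                label = label,
                both = data.frame(node = leaf_id, prob = prob, label = label,
                                  stringsAsFactors = FALSE))
  attr(out, "unseen_routed") <- unseen
  out
}

# --- cost-complexity pruning --------------------------------------------

# Materialize the subtree obtained by turning the internal nodes in
# `collapse_ids` into leaves (descendants dropped; ids renumbered preorder).
collapse_nodes <- function(tree, collapse_ids) {
  new_nodes <- list()
  next_id <- 1L
  copy <- function(id, parent) {
    nd <- tree$nodes[[id]]
    nid <- next_id
    next_id <<- nid + 1L
    nd$id <- nid
    nd$parent <- parent
    if (!nd$is_leaf && id %in% collapse_ids) {
      nd$is_leaf <- TRUE
      nd$split <- NULL
      nd$children <- NULL
    }
    new_nodes[[nid]] <<- nd
    if (!nd$is_leaf) {
      old_children <- nd$children
      left <- copy(old_children[1], nid)
      right <- copy(old_children[2], nid)
      nd$children <- c(left, right)
      new_nodes[[nid]] <<- nd
    }
    nid
  }
  copy(1L, 0L)
  tree$nodes <- new_nodes
  tree
}

# For every internal node: branch risk (counts), branch leaf count.
branch_stats <- function(nodes) {
  n_node <- length(nodes)
  r_branch <- numeric(n_node)   # misclassified counts under node
  leaves <- integer(n_node)
  order_ids <- order(vapply(nodes, `[[`, integer(1), "depth"),
                     decreasing = TRUE)
  for (id in order_ids) {
    nd <- nodes[[id]]
    if (nd$is_leaf) {
      r_branch[id] <- min(nd$n_pos, nd$n_neg)
      leaves[id] <- 1L
    } else {
      r_branch[id] <- sum(r_branch[nd$children])
      leaves[id] <- sum(leaves[nd$children])
    }
  }
  list(r_branch = r_branch, leaves = leaves)
}

#' Weakest-link cost-complexity pruning ladder
#'
#' Repeatedly collapses the internal node(s) with the smallest
#' `alpha = (R(node) - R(branch)) / (leaves(branch) - 1)`, where `R` is the
#' training misclassification risk (fraction of the training sample), down to
#' the root stump. Collapses at `alpha = 0` (splits that do not reduce
#' training risk) are folded into the first ladder entry, so the recorded
#' `alpha` values are strictly increasing and each subtree nests in its
#' predecessor.
#'
#' @param tree a `cart_tree`.
#' @return An object of class `prune_sequence`: list with `alpha` (ascending
#'   numeric vector starting at 0) and `trees` (pruned `cart_tree`s; the last
#'   is the root stump).
#' @export
cost_complexity_sequence <- function(tree) {
  N <- tree$n
  alphas <- 0
  current <- tree
  # fold zero-gain collapses into the alpha = 0 entry
  trees <- list(prune_zero_gain(tree))
  current <- trees[[1]]
  while (!current$nodes[[1]]$is_leaf) {
    bs <- branch_stats(current$nodes)
    internal <- which(!vapply(current$nodes, `[[`, logical(1), "is_leaf"))
    g <- vapply(internal, function(id) {
      nd <- current$nodes[[id]]
      (min(nd$n_pos, nd$n_neg) - bs$r_branch[id]) /
        ((bs$leaves[id] - 1L) * N)
    }, numeric(1))
    gmin <- min(g)
    weakest <- internal[g <= gmin + 1e-12]
    current <- collapse_nodes(current, weakest)
    if (gmin <= alphas[length(alphas)] + 1e-12) {
      # keep alphas strictly increasing: merge into the previous rung
      trees[[length(trees)]] <- current
    } else {
      alphas <- c(alphas, gmin)
      trees <- c(trees, list(current))
    }
  }
  structure(list(alpha = alphas, trees = trees), class = "prune_sequence")
}

# collapse every internal node whose branch does not reduce training risk
prune_zero_gain <- function(tree) {
  repeat {
    bs <- branch_stats(tree$nodes)
    internal <- which(!vapply(tree$nodes, `[[`, logical(1), "is_leaf"))
    if (!length(internal)) return(tree)
    zero <- internal[vapply(internal, function(id) {
      nd <- tree$nodes[[id]]
      min(nd$n_pos, nd$n_neg) - bs$r_branch[id] <= 1e-12
    }, logical(1))]
    if (!length(zero)) return(tree)
    tree <- collapse_nodes(tree, zero)
  }
}

#' @export
print.prune_sequence <- function(x, ...) {
  cat("Cost-complexity ladder:\n")
  for (i in seq_along(x$alpha)) {
    cat(sprintf("  alpha = %.6g: %d leaves\n", x$alpha[i],
                n_leaves(x$trees[[i]])))
  }
  invisible(x)
}

#' Prune a tree at a complexity parameter
#'
#' Returns the ladder subtree whose alpha-interval contains `cp`: the entry
#' with the largest `alpha <= cp` (ties at an exact ladder value resolve to
#' the smaller subtree). `cp = 0` returns the tree unchanged; `cp` above the
#' largest alpha returns the root stump.
#'
#' @param tree a `cart_tree`.
#' @param cp complexity parameter (>= 0) on the training-risk scale.
#' @return A pruned `cart_tree`.
#' @export
prune_tree <- function(tree, cp) {
  if (cp < 0) stop("cp must be >= 0", call. = FALSE)
  if (cp == 0) return(tree)
  prune_with_ladder(cost_complexity_sequence(tree), cp, tree)
}

prune_with_ladder <- function(ladder, cp, full_tree) {
  if (cp == 0) return(full_tree)
  k <- max(which(ladder$alpha <= cp + 1e-12))
  ladder$trees[[k]]
}

# --- cross-validation ----------------------------------------------------

# stratified fold assignment, deterministic given seed
stratified_folds <- function(y01, n_folds, seed) {
  n <- length(y01)
  if (n_folds > n) stop("n_folds exceeds the number of subjects", call. = FALSE)
  if (min(sum(y01), n - sum(y01)) < n_folds) {
    stop("too few subjects in one class to stratify the folds", call. = FALSE)
  }
  folds <- integer(n)
  with_seed(seed, {
    for (cls in c(0L, 1L)) {
      ids <- which(y01 == cls)
      ids <- ids[sample.int(length(ids))]
      folds[ids] <- rep_len(seq_len(n_folds), length(ids))
    }
  })
  folds
}

#' Cross-validated misclassification error along the pruning ladder
#'
#' Grows the full tree, extracts its alpha ladder, and evaluates candidate
#' complexity parameters (geometric midpoints of adjacent alphas; the largest
#' alpha itself for the root stump) by stratified k-fold cross-validation: in
#' each fold a tree is grown on the training portion, pruned at the candidate
#' cp, and scored on the held-out subjects.
#'
#' @inheritParams grow_tree
#' @return An object of class `cv_curve`: data.frame with `cp`, `alpha`,
#'   `n_leaves` (of the full-data subtree), `error` (held-out
#'   misclassification rate), `se` (standard error across folds), plus the
#'   full-data tree in attribute `"tree"`.
#' @export
cross_validated_error <- function(X, y, control = tree_control()) {
  full <- grow_tree(X, y, control)
  ladder <- cost_complexity_sequence(full)
  m <- length(ladder$alpha)
  cps <- if (m == 1L) 0 else {
    c(sqrt(ladder$alpha[-m] * ladder$alpha[-1]), ladder$alpha[m])
  }
  yb <- as_binary_y(y)
  folds <- stratified_folds(yb$y01, control$n_folds, control$seed)
  n <- length(yb$y01)
  fold_err <- matrix(NA_real_, control$n_folds, length(cps))
  fold_n <- integer(control$n_folds)
  for (f in seq_len(control$n_folds)) {
    tr <- folds != f
    te <- which(!tr)
    fold_n[f] <- length(te)
    ft <- grow_tree(X[tr, , drop = FALSE],
                    if (is.factor(y)) droplevels_keep(y[tr], yb$levels) else y[tr],
                    control)
    fold_ladder <- cost_complexity_sequence(ft)
    for (k in seq_along(cps)) {
      pt <- prune_with_ladder(fold_ladder, cps[k], ft)
      pred <- predict(pt, newdata = X[te, , drop = FALSE], type = "label")
      fold_err[f, k] <- mean(pred != yb$levels[yb$y01[te] + 1L])
    }
  }
  err <- colSums(fold_err * fold_n) / n
  se <- apply(fold_err, 2, stats::sd) / sqrt(control$n_folds)
  out <- data.frame(cp = cps, alpha = ladder$alpha,
                    n_leaves = vapply(ladder$trees, n_leaves, integer(1)),
                    error = err, se = se)
  attr(out, "tree") <- full
  class(out) <- c("cv_curve", "data.frame")
  out
}

droplevels_keep <- function(y, levels) factor(as.character(y), levels = levels)

#' Select a complexity parameter from a CV curve
#'
#' @param cv a `cv_curve`.
#' @param rule `"min"` (cp at the minimum cross-validated error; ties resolve
#'   to the smallest tree) or `"1se"` (largest cp within one standard error of
#'   the minimum).
#' @return The selected cp value.
#' @export
select_cp <- function(cv, rule = c("min", "1se")) {
  rule <- match.arg(rule)
  i_min <- which(cv$error <= min(cv$error) + 1e-12)
  i_min <- i_min[length(i_min)]            # ties -> larger cp, smaller tree
  if (rule == "min") return(cv$cp[i_min])
  thresh <- cv$error[i_min] + cv$se[i_min]
  max(cv$cp[cv$error <= thresh + 1e-12])
}

# --- serialization -------------------------------------------------------

#' Export a tree as a Graphviz DOT digraph
#'
#' Every node is annotated with its majority label, the positive-class
#' probability to 2 decimals, and the percentage of training subjects reaching
#' it (nearest integer). Internal nodes additionally show their split; edges
#' are labelled yes/no for the split condition.
#'
#' @param tree a `cart_tree`.
#' @return A single string containing the DOT source.
#' @export
export_dot <- function(tree) {
  lines <- c("digraph cart_tree {", "  node [shape=box];")
  for (nd in tree$nodes) {
    pct <- round(100 * nd$n / tree$n)
    ann <- sprintf("%s\\n%.2f\\n%d%%", nd$label, nd$prob, pct)
    label <- if (nd$is_leaf) ann else paste0(split_text(nd$split), "\\n", ann)
    lines <- c(lines, sprintf("  n%d [label=\"%s\"];", nd$id, label))
  }
  for (nd in tree$nodes) {
    if (!nd$is_leaf) {
      lines <- c(lines,
                 sprintf("  n%d -> n%d [label=\"yes\"];", nd$id, nd$children[1]),
                 sprintf("  n%d -> n%d [label=\"no\"];", nd$id, nd$children[2]))
    }
  }
  paste(c(lines, "}"), collapse = "\n")
}

#' Serialize a tree to JSON
#'
#' @param tree a `cart_tree`.
#' @param path optional file path; when `NULL` the JSON string is returned.
#' @return JSON string (invisibly when written to `path`).
#' @export
tree_to_json <- function(tree, path = NULL) {
  nodes <- lapply(tree$nodes, function(nd) {
    out <- list(id = nd$id, parent = nd$parent, depth = nd$depth,
                leaf = nd$is_leaf, n = nd$n, n_pos = nd$n_pos,
                n_neg = nd$n_neg, prob = nd$prob, label = nd$label)
    if (!nd$is_leaf) {
      out$split <- nd$split[!vapply(nd$split, is.null, logical(1))]
      out$children <- nd$children
    }
    out
  })
  obj <- list(classes = tree$y_levels, n = tree$n, nodes = nodes)
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}

#' Plot a classification tree
#'
#' Simple base-graphics rendering: internal nodes show their split, every node
#' shows the majority label, positive-class probability and subject
#' percentage.
#'
#' @param x a `cart_tree`.
#' @param ... passed to [graphics::text()].
#' @export
plot.cart_tree <- function(x, ...) {
  depth <- vapply(x$nodes, `[[`, integer(1), "depth")
  xpos <- numeric(length(x$nodes))
  counter <- 0
  assign_x <- function(id) {
    nd <- x$nodes[[id]]
    if (nd$is_leaf) {
      counter <<- counter + 1
      xpos[id] <<- counter
    } else {
      assign_x(nd$children[1])
      assign_x(nd$children[2])
      xpos[id] <<- mean(xpos[nd$children])
    }
  }
  assign_x(1L)
  graphics::plot(NULL, xlim = range(xpos) + c(-0.5, 0.5),
                 ylim = c(max(depth) + 0.5, -0.5), axes = FALSE,
                 xlab = "", ylab = "", main = "classification tree")
  for (nd in x$nodes) {
    if (!nd$is_leaf) {
      for (ch in nd$children) {
        graphics::segments(xpos[nd$id], depth[nd$id], xpos[ch], depth[ch],
                           col = "grey50")
      }
    }
  }
  for (nd in x$nodes) {
    lab <- sprintf("%s\n%.2f\n%d%%", nd$label, nd$prob,
                   round(100 * nd$n / x$n))
    if (!nd$is_leaf) lab <- paste0(split_text(nd$split), "\n", lab)
    graphics::text(xpos[nd$id], depth[nd$id], lab, cex = 0.7, ...)
  }
  invisible(x)
}
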