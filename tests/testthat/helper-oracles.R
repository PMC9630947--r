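# Independent brute-force references used by the oracle-equivalence tests.
# These deliberately use plain loops and direct definitions, not the package's
# vectorized code paths.

# Literal replay of greedy nearest-neighbor caliper matching: treated subjects
# in the spec's order; per treated, scan every (remaining) control, keep the K
# closest within the caliper (ties: lower control id); without replacement a
# claimed control leaves the pool.
oracle_match <- function(scores, treat, spec) {
  n <- length(scores)
  w <- if (spec$distance_scale == "logit") log(scores / (1 - scores)) else scores
  caliper <- if (identical(spec$caliper, "auto")) {
    auto_caliper(scores, spec$distance_scale)
  } else {
    spec$caliper
  }
  treated <- which(treat == 1)
  controls <- which(treat == 0)
  if (spec$order_policy == "descending_score") {
    treated <- treated[order(-w[treated], treated)]
  } else if (spec$order_policy == "random") {
    treated <- matchexplain:::with_seed(spec$seed,
                                        treated[sample.int(length(treated))])
  }
  used <- rep(FALSE, n)
  rows <- list()
  for (t in treated) {
    cand <- data.frame(id = integer(0), d = numeric(0))
    for (c_ in controls) {
      if (!spec$with_replacement && used[c_]) next
      d <- abs(w[t] - w[c_])
      if (d <= caliper) cand <- rbind(cand, data.frame(id = c_, d = d))
    }
    if (!nrow(cand)) next
    if (spec$strict_k && nrow(cand) < spec$K) next
    cand <- cand[order(cand$d, cand$id), , drop = FALSE]
    take <- head(seq_len(nrow(cand)), spec$K)
    for (i in take) {
      rows[[length(rows) + 1L]] <- data.frame(treated_id = t - 1L,
                                              control_id = cand$id[i] - 1L,
                                              distance = cand$d[i])
      used[cand$id[i]] <- TRUE
    }
  }
  if (length(rows)) do.call(rbind, rows) else {
    data.frame(treated_id = integer(0), control_id = integer(0),
               distance = numeric(0))
  }
}

# Exhaustive split search: every continuous midpoint, every categorical
# bipartition. Returns the maximal total Gini decrease and every row partition
# attaining it (as sorted left-side row indices, orientation-normalized).
oracle_best_split <- function(X, y01, minbucket) {
  n <- nrow(X)
  gini_sum <- function(nl, pl) if (nl == 0) 0 else nl - (pl^2 + (nl - pl)^2) / nl
  node_imp <- gini_sum(n, sum(y01))
  best_dec <- -Inf
  partitions <- list()
  consider <- function(left) {
    nl <- sum(left)
    if (nl < minbucket || n - nl < minbucket) return(invisible())
    dec <- node_imp - gini_sum(nl, sum(y01[left])) -
      gini_sum(n - nl, sum(y01[!left]))
    side <- sort(which(if (left[1]) left else !left))  # normalize orientation
    if (dec > best_dec + 1e-12) {
      best_dec <<- dec
      partitions <<- list(side)
    } else if (dec > best_dec - 1e-12) {
      partitions <<- c(partitions, list(side))
    }
  }
  for (j in seq_len(ncol(X))) {
    x <- X[[j]]
    if (is.numeric(x)) {
      for (cut in sort(unique(x))[-1]) consider(x < cut)
    } else {
      lev <- unique(as.character(x))
      k <- length(lev)
      if (k < 2) next
      for (m in 1:(2^(k - 1) - 1)) {
        inset <- lev[as.logical(bitwAnd(m, 2^(seq_len(k) - 1)))]
        consider(as.character(x) %in% inset)
      }
    }
  }
  list(decrease = best_dec, partitions = partitions)
}

# Enumerate every pruned subtree of a cart_tree as a set of internal nodes
# collapsed to leaves; report each subtree's misclassified count and leaf
# count.
oracle_subtrees <- function(tree) {
  nodes <- tree$nodes
  rec <- function(id) {
    nd <- nodes[[id]]
    leaf_opt <- list(list(collapsed = if (nd$is_leaf) integer(0) else id,
                          risk = min(nd$n_pos, nd$n_neg), leaves = 1L))
    if (nd$is_leaf) return(leaf_opt)
    left <- rec(nd$children[1])
    right <- rec(nd$children[2])
    combos <- list()
    for (a in left) for (b in right) {
      combos[[length(combos) + 1L]] <- list(
        collapsed = c(a$collapsed, b$collapsed),
        risk = a$risk + b$risk, leaves = a$leaves + b$leaves)
    }
    c(leaf_opt, combos)
  }
  rec(1L)
}

# training misclassification risk (fraction) and leaves of a cart_tree
tree_cost <- function(tree, cp) {
  leaves <- Filter(function(nd) nd$is_leaf, tree$nodes)
  risk <- sum(vapply(leaves, function(nd) min(nd$n_pos, nd$n_neg), numeric(1)))
  risk / tree$n + cp * length(leaves)
}

# small random cohort-like data.frame for fuzzing
random_dataset <- function(n, n_num = 2, n_cat = 1, k = 3) {
  out <- list()
  for (j in seq_len(n_num)) out[[paste0("x", j)]] <- round(runif(n, 0, 10), 1)
  for (j in seq_len(n_cat)) {
    out[[paste0("g", j)]] <- factor(sample(letters[1:k], n, replace = TRUE))
  }
  as.data.frame(out)
}

n_leaves_of <- function(tree) {
  sum(vapply(tree$nodes, `[[`, logical(1), "is_leaf"))
}

hn_small <- function(n = 400, seed = 11) {
  generate_cohort(cohort_preset("hn_ncdb", n = n, seed = seed))
}

# planted exclusion rule: subjects over 80 go unmatched with probability 0.8,
# everyone else with probability 0.1. The label stream is decoupled from the
# cohort-generation stream (offset seed) so the Bernoulli draws are
# independent of the age quantile draws.
with_planted_rule <- function(cohort, seed) {
  matchexplain:::with_seed(seed + 500000L, {
    p_out <- ifelse(cohort$age > 80, 0.8, 0.1)
    factor(ifelse(rbinom(nrow(cohort), 1, p_out) == 1, "out", "in"),
           levels = c("out", "in"))
  })
}
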