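test_that("gini impurity matches the closed form", {
  expect_equal(gini_impurity(5, 0), 0)
  expect_equal(gini_impurity(5, 5), 0.5)
  expect_equal(gini_impurity(3, 1), 0.375)
  expect_equal(gini_impurity(c(3, 1)), 0.375)
  expect_error(gini_impurity(0, 0), "not both zero")
})

test_that("best_split finds the midpoint cut on a separable toy", {
  X <- data.frame(x = c(1, 2, 3, 4))
  y <- factor(c("out", "out", "in", "in"), levels = c("out", "in"))
  sp <- best_split(X, y, tree_control(minsplit = 2, minbucket = 1))
  expect_equal(sp$var, "x")
  expect_equal(sp$threshold, 2.5)
  expect_equal(sp$decrease, 4 * 0.5)  # children pure: full impurity removed
  # constant y or constant x -> no split
  expect_null(best_split(X, factor(rep("in", 4), levels = c("out", "in")),
                         tree_control(minsplit = 2, minbucket = 1)))
  expect_null(best_split(data.frame(x = rep(1, 4)), y,
                         tree_control(minsplit = 2, minbucket = 1)))
})

test_that("best_split equals the exhaustive oracle on random data", {
  set.seed(42)
  ctrl <- tree_control(minsplit = 4, minbucket = 2, cp_grow = 0)
  for (rep in 1:40) {
    n <- sample(8:50, 1)
    X <- random_dataset(n, n_num = 2, n_cat = 1, k = sample(2:4, 1))
    y01 <- rbinom(n, 1, 0.5)
    if (sum(y01) %in% c(0, n)) next
    y <- factor(ifelse(y01 == 1, "in", "out"), levels = c("out", "in"))
    sp <- best_split(X, y, ctrl)
    want <- oracle_best_split(X, y01, ctrl$minbucket)
    if (is.null(sp)) {
      expect_lte(want$decrease, 1e-12)
      next
    }
    expect_equal(sp$decrease, want$decrease, tolerance = 1e-9)
    left <- if (sp$type == "continuous") {
      X[[sp$var]] < sp$threshold
    } else {
      as.character(X[[sp$var]]) %in% sp$levels_left
    }
    side <- sort(which(if (left[1]) left else !left))
    expect_true(any(vapply(want$partitions, identical, logical(1), side)),
                label = sprintf("split partition matches an argmax (rep %d)", rep))
  }
})

test_that("grow_tree reconstructs a two-stratum rule exactly", {
  X <- data.frame(age = c(rep(60, 10), rep(85, 10)))
  y <- factor(c(rep("in", 10), rep("out", 10)), levels = c("out", "in"))
  tr <- grow_tree(X, y, tree_control(minsplit = 4, minbucket = 2))
  expect_equal(length(tr$nodes), 3L)
  expect_equal(tr$nodes[[1]]$split$threshold, 72.5)
  expect_equal(tr$nodes[[2]]$prob, 1)
  expect_equal(tr$nodes[[3]]$prob, 0)
  # maxdepth 0 -> root only, predicting the overall in-fraction
  stump <- grow_tree(X, y, tree_control(maxdepth = 0))
  expect_equal(length(stump$nodes), 1L)
  expect_equal(stump$nodes[[1]]$prob, 0.5)
  # no admissible split anywhere -> root only ("no tree grew")
  noise <- grow_tree(data.frame(x = rep(1, 30)),
                     factor(rep(c("in", "out"), 15), levels = c("out", "in")))
  expect_equal(length(noise$nodes), 1L)
})

test_that("the 4-subject stump yields a single pruning alpha of 0.5", {
  X <- data.frame(x = c(1, 2, 3, 4))
  y <- factor(c("out", "out", "in", "in"), levels = c("out", "in"))
  tr <- grow_tree(X, y, tree_control(minsplit = 2, minbucket = 1))
  expect_equal(length(tr$nodes), 3L)
  seqs <- cost_complexity_sequence(tr)
  expect_equal(seqs$alpha, c(0, 0.5))
  expect_equal(n_leaves_of(seqs$trees[[2]]), 1L)
  # prune at cp below/above the alpha
  expect_equal(length(prune_tree(tr, 0.4)$nodes), 3L)
  expect_equal(length(prune_tree(tr, 0.6)$nodes), 1L)
  expect_equal(length(prune_tree(tr, 0)$nodes), 3L)   # identity at cp = 0
  expect_equal(length(prune_tree(tr, 1)$nodes), 1L)   # root stump at cp = 1
})

test_that("root-only trees have a trivial ladder", {
  X <- data.frame(x = rep(1, 10))
  y <- factor(rep(c("in", "out"), 5), levels = c("out", "in"))
  tr <- grow_tree(X, y)
  seqs <- cost_complexity_sequence(tr)
  expect_equal(seqs$alpha, 0)
  expect_equal(length(seqs$trees), 1L)
})

test_that("pruning ladder alphas strictly increase and subtrees nest", {
  set.seed(7)
  for (rep in 1:10) {
    n <- 80
    X <- random_dataset(n, 2, 1)
    y <- factor(ifelse(rbinom(n, 1, plogis(X$x1 - 5)) == 1, "in", "out"),
                levels = c("out", "in"))
    tr <- grow_tree(X, y, tree_control(minsplit = 6, minbucket = 3,
                                       cp_grow = 0, maxdepth = 5))
    seqs <- cost_complexity_sequence(tr)
    expect_true(all(diff(seqs$alpha) > 0))
    sizes <- vapply(seqs$trees, function(t) length(t$nodes), integer(1))
    expect_true(all(diff(sizes) < 0) || length(sizes) == 1L)
    expect_true(seqs$trees[[length(seqs$trees)]]$nodes[[1]]$is_leaf)
    # nesting: each subtree's splits are a subset of its predecessor's
    split_keys <- function(t) {
      vapply(Filter(function(nd) !nd$is_leaf, t$nodes), function(nd) {
        paste(nd$split$var, nd$split$threshold,
              paste(nd$split$levels_left, collapse = "|"), nd$n, nd$n_pos)
      }, character(1))
    }
    for (i in seq_along(seqs$trees)[-1]) {
      expect_true(all(split_keys(seqs$trees[[i]]) %in%
                        split_keys(seqs$trees[[i - 1]])))
    }
  }
})

test_that("prune attains the minimal cost complexity over all enumerated subtrees", {
  set.seed(99)
  checked <- 0
  for (rep in 1:12) {
    n <- sample(40:70, 1)
    X <- random_dataset(n, 2, 1)
    y <- factor(ifelse(rbinom(n, 1, 0.5) == 1, "in", "out"),
                levels = c("out", "in"))
    tr <- grow_tree(X, y, tree_control(minsplit = 4, minbucket = 2,
                                       cp_grow = 0, maxdepth = 4))
    internal <- sum(!vapply(tr$nodes, `[[`, logical(1), "is_leaf"))
    if (internal < 1 || internal > 10) next
    subs <- oracle_subtrees(tr)
    for (cp in c(0, 0.001, 0.005, 0.01, 0.02, 0.05, 0.1, 0.3, 0.6, 1)) {
      best <- min(vapply(subs, function(s) s$risk / n + cp * s$leaves,
                         numeric(1)))
      got <- tree_cost(prune_tree(tr, cp), cp)
      expect_equal(got, best, tolerance = 1e-12,
                   label = sprintf("cp = %g, rep %d", cp, rep))
      checked <- checked + 1
    }
  }
  expect_gte(checked, 50)
})

test_that("training-set predictions reproduce leaf counts exactly", {
  ch <- hn_small(300)
  y <- factor(ifelse(ch$age > 80, "out", "in"), levels = c("out", "in"))
  tr <- grow_tree(ch[c("age", "site", "nstage")], y)
  pred <- predict(tr, ch[c("age", "site", "nstage")], type = "both")
  for (id in unique(pred$node)) {
    nd <- tr$nodes[[id]]
    sel <- pred$node == id
    expect_equal(sum(sel), nd$n)
    expect_equal(sum(y[sel] == "in"), nd$n_pos)
    expect_equal(unique(pred$prob[sel]), nd$prob)
  }
  # leaf counts -> probabilities and labels
  leaf <- Filter(function(nd) nd$is_leaf, tr$nodes)[[1]]
  expect_equal(leaf$prob, leaf$n_pos / leaf$n)
})

test_that("unseen categorical levels are routed to the majority child and flagged", {
  X <- data.frame(g = factor(c(rep("a", 30), rep("b", 20))))
  y <- factor(c(rep("in", 30), rep("out", 20)), levels = c("out", "in"))
  tr <- grow_tree(X, y, tree_control(minsplit = 4, minbucket = 2))
  p <- predict(tr, data.frame(g = "zzz"), type = "prob")
  expect_true(attr(p, "unseen_routed"))
  expect_equal(unname(p[1]), 1)  # larger child is the "a" leaf
})

test_that("DOT export annotates every node with label, probability and percentage", {
  X <- data.frame(age = c(rep(60, 30), rep(85, 10)))
  y <- factor(c(rep("in", 30), rep("out", 10)), levels = c("out", "in"))
  tr <- grow_tree(X, y, tree_control(minsplit = 4, minbucket = 2))
  dot <- export_dot(tr)
  expect_match(dot, "^digraph")
  expect_equal(length(gregexpr("label=\"", dot)[[1]]),
               length(tr$nodes) + 2L * sum(!vapply(tr$nodes, `[[`,
                                                   logical(1), "is_leaf")))
  expect_match(dot, "age < 72\\.5\\\\nin\\\\n0\\.75\\\\n100%", fixed = FALSE)
  expect_match(dot, "in\\\\n1\\.00\\\\n75%")
  expect_match(dot, "out\\\\n0\\.00\\\\n25%")
  # root-only export has exactly one node line
  stump <- grow_tree(X, y, tree_control(maxdepth = 0))
  expect_equal(length(gregexpr("label=\"", export_dot(stump))[[1]]), 1L)
})

test_that("cross-validation is deterministic and finds separable structure", {
  set.seed(15)
  n <- 300
  X <- data.frame(x = runif(n, 0, 10))
  y <- factor(ifelse(X$x > 5, "in", "out"), levels = c("out", "in"))
  ctrl <- tree_control(n_folds = 5, seed = 8)
  cv1 <- cross_validated_error(X, y, ctrl)
  cv2 <- cross_validated_error(X, y, ctrl)
  expect_equal(as.data.frame(cv1), as.data.frame(cv2))
  expect_lt(min(cv1$error), 0.02)
  best <- prune_tree(attr(cv1, "tree"), select_cp(cv1, "min"))
  expect_gt(length(best$nodes), 1L)
})

test_that("pure-noise labels cross-validate to the majority-rule error", {
  set.seed(16)
  n <- 400
  X <- data.frame(x = runif(n), g = factor(sample(letters[1:3], n, TRUE)))
  y01 <- rbinom(n, 1, 0.35)
  y <- factor(ifelse(y01 == 1, "in", "out"), levels = c("out", "in"))
  cv <- cross_validated_error(X, y, tree_control(n_folds = 5, seed = 2))
  base_rate <- min(mean(y01), 1 - mean(y01))
  se <- sqrt(base_rate * (1 - base_rate) / n)
  expect_lt(abs(min(cv$error) - base_rate), 3 * se + max(cv$se))
})

test_that("grown trees agree with rpart on a clean root split", {
  skip_if_not_installed("rpart")
  set.seed(44)
  n <- 500
  X <- data.frame(age = round(runif(n, 60, 90)), z = rnorm(n))
  y01 <- rbinom(n, 1, ifelse(X$age > 78, 0.85, 0.15))
  y <- factor(ifelse(y01 == 1, "in", "out"), levels = c("out", "in"))
  mine <- grow_tree(X, y, tree_control(maxdepth = 1))
  ref <- rpart::rpart(y ~ age + z, data = cbind(X, y = y), method = "class",
                      control = rpart::rpart.control(minsplit = 20,
                                                     minbucket = 7,
                                                     cp = 0.01, maxdepth = 1,
                                                     xval = 0))
  expect_equal(mine$nodes[[1]]$split$var, "age")
  expect_equal(mine$nodes[[1]]$split$threshold,
               unname(ref$splits[1, "index"]), tolerance = 1e-9)
})
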