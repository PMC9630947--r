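toy_scores <- c(A = 0.50, B = 0.80, c1 = 0.48, c2 = 0.79, c3 = 0.10)
toy_treat <- c(1, 1, 0, 0, 0)

test_that("the worked 5-subject match reproduces the hand enumeration", {
  spec <- match_spec(K = 1, with_replacement = FALSE, caliper = 0.05,
                     distance_scale = "raw", order_policy = "descending_score")
  res <- nearest_neighbor_match(unname(toy_scores), toy_treat, spec)
  # B (0.80) processed first -> c2 at 0.01; then A -> c1 at 0.02; c3 unmatched
  expect_equal(res$pairs$treated_id, c(1L, 0L))
  expect_equal(res$pairs$control_id, c(3L, 2L))
  expect_equal(res$pairs$distance, c(0.01, 0.02), tolerance = 1e-12)
  expect_identical(as.character(res$inclusion), c("in", "in", "in", "in", "out"))
  expect_equal(res$n_matched_treated, 2L)
  expect_equal(res$n_distinct_controls_used, 2L)
})

test_that("auto caliper equals 0.2 sample SD on the chosen scale", {
  s <- c(0.2, 0.4, 0.6, 0.8)
  lo <- log(s / (1 - s))
  expect_equal(auto_caliper(s, "logit"), 0.2 * sd(lo), tolerance = 1e-12)
  expect_equal(round(auto_caliper(s, "logit"), 4), 0.2359)
  expect_equal(auto_caliper(s, "raw"), 0.2 * sd(s), tolerance = 1e-12)
  # symmetry of the logit: invariant under score reflection
  expect_equal(auto_caliper(1 - s, "logit"), auto_caliper(s, "logit"),
               tolerance = 1e-12)
  expect_error(auto_caliper(rep(0.5, 4), "logit"), "degenerate")
  expect_error(auto_caliper(0.5, "raw"), "at least 2")
})

test_that("a treated subject with no in-caliper control is dropped from the pairs", {
  scores <- c(0.9, 0.1, 0.12)   # treated 0.9 far from both controls
  res <- nearest_neighbor_match(scores, c(1, 0, 0),
                                match_spec(caliper = 0.05,
                                           distance_scale = "raw",
                                           with_replacement = FALSE))
  expect_equal(nrow(res$pairs), 0L)
  expect_true(all(res$inclusion == "out"))
  expect_equal(res$n_unmatched_treated, 1L)
})

test_that("with replacement one control can serve two treated subjects", {
  scores <- c(0.40, 0.60, 0.50)  # control exactly between the two treated
  res <- nearest_neighbor_match(scores, c(1, 1, 0),
                                match_spec(K = 1, with_replacement = TRUE,
                                           caliper = 0.2,
                                           distance_scale = "raw"))
  expect_equal(nrow(res$pairs), 2L)
  expect_equal(res$n_distinct_controls_used, 1L)
  expect_true(all(res$pairs$control_id == 2L))
})

test_that("inclusion labels partition the cohort", {
  res <- list(pairs = data.frame(treated_id = c(0L, 1L), control_id = c(3L, 3L)))
  lab <- label_inclusion(res, 5)
  expect_identical(as.character(lab), c("in", "in", "out", "in", "out"))
  empty <- list(pairs = data.frame(treated_id = integer(0),
                                   control_id = integer(0)))
  expect_true(all(label_inclusion(empty, 4) == "out"))
  full <- list(pairs = data.frame(treated_id = 0:1, control_id = 2:3))
  expect_true(all(label_inclusion(full, 4) == "in"))
  bad <- list(pairs = data.frame(treated_id = 0L, control_id = 9L))
  expect_error(label_inclusion(bad, 5), "\\[0, n\\)")
})

test_that("greedy matching equals the brute-force replay on random instances", {
  set.seed(123)
  for (rep in 1:60) {
    n <- sample(4:20, 1)
    treat <- integer(n)
    treat[sample(n, sample(1:(n - 1), 1))] <- 1L
    scores <- runif(n, 0.02, 0.98)
    spec <- match_spec(K = sample(1:2, 1),
                       with_replacement = sample(c(TRUE, FALSE), 1),
                       caliper = sample(c(0.1, 0.5, 2), 1),
                       distance_scale = sample(c("raw", "logit"), 1),
                       order_policy = "descending_score")
    got <- nearest_neighbor_match(scores, treat, spec)$pairs
    want <- oracle_match(scores, treat, spec)
    expect_equal(got, want, tolerance = 1e-12,
                 label = sprintf("instance %d", rep))
  }
})

test_that("caliper soundness and completeness hold on fuzzed instances", {
  set.seed(321)
  for (rep in 1:200) {
    n <- sample(5:30, 1)
    treat <- integer(n)
    treat[sample(n, sample(1:(n - 1), 1))] <- 1L
    scores <- runif(n, 0.05, 0.95)
    spec <- match_spec(K = 1, with_replacement = FALSE,
                       caliper = runif(1, 0.02, 0.5),
                       distance_scale = "raw")
    res <- nearest_neighbor_match(scores, treat, spec)
    # soundness: every emitted distance within the caliper
    expect_true(all(res$pairs$distance <= spec$caliper + 1e-12))
    # completeness: an unmatched treated had no unused in-caliper control left
    used <- res$pairs$control_id
    unmatched <- setdiff(which(treat == 1L) - 1L, res$pairs$treated_id)
    free_controls <- setdiff(which(treat == 0L) - 1L, used)
    for (t in unmatched) {
      if (length(free_controls)) {
        dmin <- min(abs(scores[t + 1L] - scores[free_controls + 1L]))
        expect_gt(dmin, spec$caliper)
      }
    }
    # conservation
    expect_equal(sum(res$inclusion == "in") + sum(res$inclusion == "out"), n)
  }
})

test_that("with replacement the pairs are order-policy invariant when neighbors are unique", {
  set.seed(77)
  scores <- round(runif(30, 0.1, 0.9), 3)
  scores <- scores + seq_along(scores) * 1e-6  # break exact ties
  treat <- rep(c(1, 0, 0), 10)
  specs <- lapply(c("descending_score", "data_order", "random"), function(p) {
    match_spec(K = 1, with_replacement = TRUE, caliper = 0.3,
               distance_scale = "raw", order_policy = p, seed = 5)
  })
  results <- lapply(specs, function(s) {
    p <- nearest_neighbor_match(scores, treat, s)$pairs
    p[order(p$treated_id), ]
  })
  expect_equal(results[[1]], results[[2]], ignore_attr = TRUE)
  expect_equal(results[[1]], results[[3]], ignore_attr = TRUE)
})

test_that("pairs and labels write valid CSV", {
  res <- nearest_neighbor_match(unname(toy_scores), toy_treat,
                                match_spec(K = 1, with_replacement = FALSE,
                                           caliper = 0.05,
                                           distance_scale = "raw"))
  pp <- withr::local_tempfile(fileext = ".csv")
  lp <- withr::local_tempfile(fileext = ".csv")
  write_pairs(res, pp)
  write_labels(res, lp)
  expect_equal(nrow(read.csv(pp)), 2L)
  labs <- read.csv(lp)
  expect_identical(names(labs), c("subject_id", "label"))
  expect_equal(sum(labs$label == "in"), 4L)
})
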