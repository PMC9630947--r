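test_that("quartile discretization matches interpolated quantiles", {
  enc <- discretize(1:8, "quartile")
  expect_equal(enc$edges, c(2.75, 4.5, 6.25))
  expect_equal(encode_bins(enc, 5), 3L)
  expect_equal(encode_bins(enc, -10), 1L)   # below every edge
  expect_equal(encode_bins(enc, 100), 4L)
  # monotone: larger values never map to lower bins
  v <- sort(runif(50, -5, 15))
  expect_true(all(diff(encode_bins(enc, v)) >= 0))
  expect_error(discretize(rep(1, 10), "quartile"), "4 distinct")
  # "none" mode standardizes
  enc2 <- discretize(c(2, 4, 6, 8), "none")
  expect_equal(encode_bins(enc2, enc2$mean), 0)
  expect_error(discretize(rep(3, 5), "none"), "constant")
})

test_that("perturbation returns the instance first and is deterministic", {
  ch <- hn_small(200)
  cfg <- lime_config(n_permutations = 100, seed = 9)
  smry <- lime_training_summary(ch, c("age", "site", "sex"), cfg)
  inst <- ch[5, c("age", "site", "sex")]
  p1 <- perturb(inst, smry, cfg)
  p2 <- perturb(inst, smry, cfg)
  expect_identical(p1, p2)
  expect_equal(nrow(p1$data), 100L)
  expect_equal(unname(p1$design[1, ]), c(1, 1, 1))
  expect_equal(p1$distances[1], 0)
  expect_true(all(p1$distances >= 0 & p1$distances <= 1))
})

test_that("indicator frequency tracks the training marginal", {
  n <- 6000
  train <- data.frame(g = factor(rep(c("yes", "no"), n / 2)))
  cfg <- lime_config(n_permutations = 5000, seed = 4)
  smry <- lime_training_summary(train, "g", cfg)
  p <- perturb(data.frame(g = factor("yes", levels = c("no", "yes"))), smry, cfg)
  expect_lt(abs(mean(p$design[-1, 1]) - 0.5), 3 * sqrt(0.25 / 4999))
})

test_that("the similarity kernel has the right fixed points", {
  expect_equal(kernel_similarity(0, 2), 1)
  expect_equal(kernel_similarity(2, 2), exp(-1))
  expect_equal(kernel_similarity(c(0.5, 3), 1e9), c(1, 1), tolerance = 1e-12)
  expect_error(kernel_similarity(-1, 1), ">= 0")
  expect_error(kernel_similarity(1, 0), "> 0")
})

test_that("a linear black box is recovered by the local surrogate", {
  set.seed(2)
  train <- data.frame(z1 = as.numeric(scale(rnorm(500))),
                      z2 = as.numeric(scale(rnorm(500))))
  bb <- function(d) 2 * d$z1 - d$z2 + 3
  cfg <- lime_config(n_permutations = 5000, kernel_width = 1e6,
                     n_features = 2, discretizer = "none", seed = 11)
  smry <- lime_training_summary(train, c("z1", "z2"), cfg)
  ex <- explain_instance(bb, train[1, ], smry, cfg, subject_id = 0L)
  w <- ex$features$weight[match(c("z1", "z2"), ex$features$column)]
  expect_lt(max(abs(w - c(2, -1))), 0.05)
  expect_gte(ex$explanation_fit, 0.99)
  # width-invariance for an exactly linear target
  cfg2 <- lime_config(n_permutations = 5000, kernel_width = 0.5,
                      n_features = 2, discretizer = "none", seed = 11)
  ex2 <- explain_instance(bb, train[1, ], smry, cfg2, subject_id = 0L)
  w2 <- ex2$features$weight[match(c("z1", "z2"), ex2$features$column)]
  expect_lt(max(abs(w2 - w)), 1e-6)
})

test_that("a constant black box yields zero weights and zero explanation fit", {
  ch <- hn_small(150)
  cfg <- lime_config(n_permutations = 200, seed = 3)
  smry <- lime_training_summary(ch, c("age", "site"), cfg)
  ex <- explain_instance(function(d) rep(0.7, nrow(d)),
                         ch[1, c("age", "site")], smry, cfg, subject_id = 0L)
  expect_true(all(ex$features$weight == 0))
  expect_equal(ex$explanation_fit, 0)
  expect_equal(ex$predicted_label, "in")
})

test_that("an age-only tree black box puts the top weight on the age bin", {
  ch <- generate_cohort(cohort_preset("hn_ncdb", n = 2000, seed = 13))
  lab <- with_planted_rule(ch, seed = 13)
  covs <- c("age", "sex", "site", "nstage")
  tr <- fit_population_explainer(ch, lab, covs, tree_control(seed = 13))
  expect_equal(tr$nodes[[1]]$split$var, "age")
  bb <- function(d) predict(tr, newdata = d, type = "prob")
  cfg <- lime_config(n_permutations = 2000, seed = 17)
  smry <- lime_training_summary(ch, covs, cfg)
  old <- which(ch$age > 82)[1]
  ex <- explain_instance(bb, ch[old, covs], smry, cfg,
                         subject_id = old - 1L)
  expect_equal(ex$features$column[1], "age")
  expect_equal(ex$predicted_label, "out")
  # the age bin carries weight toward "out": negative and labelled supportive
  expect_lt(ex$features$weight[1], 0)
  expect_equal(ex$features$direction[1], "supports")
})

test_that("explanations are deterministic and summaries group correctly", {
  ch <- hn_small(200)
  cfg <- lime_config(n_permutations = 300, seed = 5)
  smry <- lime_training_summary(ch, c("age", "site"), cfg)
  bb <- function(d) plogis((80 - d$age) / 5)
  e1 <- explain_instance(bb, ch[2, c("age", "site")], smry, cfg, subject_id = 1L)
  e2 <- explain_instance(bb, ch[2, c("age", "site")], smry, cfg, subject_id = 1L)
  expect_equal(e1[setdiff(names(e1), "subject_id")],
               e2[setdiff(names(e2), "subject_id")])
  # group summary: means per inclusion group, invariant to list order
  e3 <- explain_instance(bb, ch[3, c("age", "site")], smry, cfg, subject_id = 2L)
  inc <- factor(c("out", "in", "out", rep("in", 197)), levels = c("out", "in"))
  s1 <- summarize_explanations(list(e1, e3), inc)
  s2 <- summarize_explanations(list(e3, e1), inc)
  expect_equal(s1, s2)
  expect_equal(s1$mean_fit[s1$group == "in"], e1$explanation_fit)
  expect_equal(s1$mean_fit[s1$group == "out"], e3$explanation_fit)
  one <- summarize_explanations(list(e1), inc)
  expect_true(is.na(one$mean_fit[one$group == "out"]))
  expect_equal(one$mean_fit[one$group == "in"], e1$explanation_fit)
})

test_that("black-box failures on perturbed rows are dropped with a warning", {
  ch <- hn_small(100)
  cfg <- lime_config(n_permutations = 50, seed = 8)
  smry <- lime_training_summary(ch, c("age", "site"), cfg)
  flaky <- function(d) {
    if (nrow(d) > 1) stop("no vectorized path")
    if (d$age[1] > 85) stop("boom")
    plogis((80 - d$age[1]) / 5)
  }
  expect_warning(
    ex <- explain_instance(flaky, ch[1, c("age", "site")], smry, cfg,
                           subject_id = 0L),
    "dropped")
  expect_s3_class(ex, "lime_explanation")
  always_fails <- function(d) stop("nope")
  expect_error(
    suppressWarnings(explain_instance(always_fails, ch[1, c("age", "site")],
                                      smry, cfg, subject_id = 0L)),
    "more than half")
})

test_that("explanations serialize to JSON", {
  ch <- hn_small(100)
  cfg <- lime_config(n_permutations = 100, seed = 2)
  smry <- lime_training_summary(ch, c("age", "site"), cfg)
  ex <- explain_instance(function(d) plogis((80 - d$age) / 5),
                         ch[1, c("age", "site")], smry, cfg, subject_id = 0L)
  path <- withr::local_tempfile(fileext = ".json")
  explanations_to_json(list(ex), path)
  back <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(back$subject_id, 0L)
  expect_equal(back$explanation_fit, ex$explanation_fit, tolerance = 1e-12)
})
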