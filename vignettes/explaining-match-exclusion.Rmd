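---
title: "Explaining who survives propensity-score matching"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Explaining who survives propensity-score matching}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(matchexplain)
```

## The problem

Matching on the propensity score `e(Z) = P(T = 1 | Z)` discards treated
subjects that find no control within the caliper, and (without replacement)
controls already claimed by someone else. The retained subjects define the
subpopulation the causal estimate actually covers; the discarded ones are the
subjects for whom the data support no comparison. `matchexplain` treats the
matching stage itself as a black box and models its in/out decision twice:
globally with a pruned classification tree, and per subject with a local
linear surrogate. Neither explainer changes the analysis — they describe it.

The method assumes complete data (no surrogate splits; missingness, if
present, should be coded as a category), a binary treatment (multi-arm
designs are handled as pairwise comparisons, as the shipped glioblastoma-like
preset illustrates), and covariates that are either continuous or
categorical.

## The pipeline, stage by stage

**Propensity estimation.** Natively: maximum-likelihood logistic regression
on the dummy-coded design (IRLS with step-halving; convergence when every
component of the score equation `X'(y − p)` is below `tol = 1e-8`, default
cap 50 iterations; rank-deficient designs are an error naming the collinear
columns; separation — fitted probabilities within `tol` of 0/1 or a diverging
coefficient norm — is a warning, and the clipped scores are still usable for
matching); a classification tree whose terminal-node treated fractions become
the scores, pruned at minimum cross-validated error; or bagged trees with
per-split feature subsampling, averaging leaf fractions over bootstrap
resamples. Estimators the package does not implement (covariate-balancing
scores, SVMs, boosted ensembles) enter through an external-scores CSV, since
every downstream stage is estimator-agnostic. All emitted scores are clipped
to `[1e-6, 1 − 1e-6]` so logit transforms are always defined.

**Matching.** Greedy K:1 nearest-neighbor within a caliper. Defaults and the
reasoning behind them:

* `distance_scale = "logit"` — score distributions are compressed near 0/1;
  the logit scale is the common recommendation and both scales are offered
  because analyses rarely state which they used.
* `caliper = "auto"` = 0.2 × SD of the (logit) scores — the standard
  caliper rule; a numeric override exists. All-equal scores make the auto
  caliper zero, which is an error rather than a silent match-everything.
* `with_replacement = TRUE` — matching schemes are described both ways in the
  applied literature (classical greedy 1-1 removes a used control; reported
  registry analyses often reuse controls). The flag covers both; the default
  follows the with-replacement convention, and a control reused by several
  treated subjects counts once in the "in" group.
* `order_policy = "descending_score"` — treated subjects with high scores are
  hardest to match, so they pick first (the common greedy heuristic);
  `data_order` and seeded `random` are available because the processing order
  matters without replacement.
* Partial matches: a treated subject keeps however many (1..K) in-caliper
  controls it finds; the all-or-nothing alternative is `strict_k = TRUE`. The
  permissive default discards less information.
* Distance ties break to the lower control id, making results deterministic.

**Population explainer.** A binary classification tree for in/out: Gini
impurity splits (the classification default in standard recursive
partitioning software; continuous cutpoints at midpoints between adjacent
observed values, categorical bipartitions searched exhaustively up to 12
observed levels and by class-proportion ordering — exact for a binary
outcome — above), growth gated by `minsplit = 20`, `minbucket = 7`,
`maxdepth = 30` and a relative impurity-improvement threshold
`cp_grow = 0.01`, then weakest-link cost-complexity pruning on the
training misclassification risk. The pruning cp is chosen at the *minimum*
of the stratified 10-fold cross-validated error (ties toward the smaller
tree); the more conservative 1-SE rule is available as an option. Split ties
break to the earlier covariate and smaller cutpoint. `prune(tree, 0)` returns
the tree unchanged by convention; collapses that do not change training risk
are folded into the ladder's first rung so the recorded alphas strictly
increase. Single-class labels (everything matched, or nothing) yield a
flagged root stump instead of an error. A balance table accompanies the tree:
Welch t-tests for continuous covariates, Pearson chi-square without
continuity correction for categorical ones (common table-one conventions;
reports print mean (sd) rounded, machine output keeps full precision;
zero-variance comparisons return p = 1 when the group means coincide).

**Individual explainer.** For one subject: draw `n_permutations = 5000` rows
(the first is the subject itself), resampling each covariate independently
from its training marginal; represent each row by one indicator per covariate
— "falls in the subject's own quartile bin / level" — or by the z-scored
value when `discretizer = "none"`; weight rows by
`exp(−d²/width²)` with `d` the design-space Euclidean distance scaled by
`√p` and default `width = 0.75·√p` (the convention of the reference LIME
implementation; neither kernel family nor width is canonical); fit weighted
least squares on all columns, keep the `n_features = 5` largest absolute
coefficients, refit, and report the weights, the intercept and the weighted
R² ("explanation fit", defined as 0 for a zero-variance response). A weight
"supports" the predicted label when its sign pushes the inclusion probability
toward that label. Quartile binning echoes the binned age features that such
explanations typically surface; numeric columns with fewer than four distinct
values are treated as categorical. The explainer targets the *tree's*
predicted inclusion probability, not the realized in/out label: the question
answered is how the population model reached its decision, and this keeps the
procedure well-defined for subjects the tree misclassifies. Ridge
regularization is available (`ridge > 0`) but off by default — ordinary WLS
keeps the linear-recovery property exact.

## The synthetic generator

Real registry extracts behind the motivating analyses are restricted, so the
generator stands in for them: covariates drawn independently (truncated
normal for continuous, multinomial for categorical), treatment assigned by a
logistic model on the dummy-coded design — exactly the form the logistic
estimator fits, deliberately, so parameter recovery is a meaningful test.
The `hn_ncdb` preset (n = 4042) reproduces published marginals: treated
fraction 0.63 (intercept calibrated once by Monte Carlo), cancer-site split
~50.9/35.9/13.2% (printed site percentages renormalized to sum to 1), ages
71–90 as integer years. The `gbm_ncdb` preset (n = 10128) represents the
combined-modality vs radiation-alone arm of a three-arm comparison, adding
surgery and year-of-diagnosis covariates, treated fraction 0.833; its
truncated-normal age reproduces the printed age-category fractions only
approximately (.34/.29/.20/.18 against .37/.28/.20/.15) — a single truncated
normal cannot match them exactly, and no joint distribution is published.

What the generator does *not* emulate: covariate dependence (a real cohort's
age–comorbidity–stage correlations), outcome/survival structure, missing
data, calendar drift. Passing tests therefore demonstrate algorithmic
correctness and recovery under a well-specified model, not performance on
real registry data.

## Numerical and testing choices

Floating-point ties at the caliper boundary and in split search are resolved
with a 1e-12 tolerance. Fold assignment is stratified by class and seeded;
every seeded routine saves and restores the caller's RNG state. Pipeline
stage seeds derive from the global seed as `(seed·131 + stage) mod (2³¹−2)
+ 1` so any stage can be replayed in isolation; bundle files are written with
17-significant-digit floats and LF endings, making repeat runs byte-identical.

The test suite checks the matching, split and pruning code against literal
brute-force oracles (replayed greedy matching on instances of n ≤ 20;
exhaustive cutpoint/bipartition search at n ≤ 50; full enumeration of pruned
subtrees for trees with ≤ 10 internal nodes), recovers planted structure
(logistic coefficients at n = 20000 within ±0.1; an age-over-80 exclusion
rule at n = 4000 across 50 label seeds, root threshold within ±2 years; an
exactly linear black box recovered by the surrogate to ±0.05 with R² ≥ 0.99),
and verifies hand-computed micro-examples (Gini values, a pruning alpha of
0.5, the 0.2359 auto caliper, a chi-square of 6.6667). These problem sizes
keep the default suite under a minute while leaving the binomial/recovery
tolerances (3 SDs, ±0.1, ±2 years) comfortably wide.

## Known limitations

* Greedy matching only: no optimal (network-flow), Mahalanobis,
  exact-within-stratum or full matching.
* No surrogate splits, regression trees or variable-importance measures in
  the tree engine; complete data are required.
* The local surrogate perturbs covariates independently; correlated
  covariates can receive diluted or shared weights.
* The balance table compares in vs out, not treated vs control — covariate
  balance diagnostics between treatment arms are a different (standard)
  report and are out of scope.
* With a rare treated group, most controls go unmatched and the in/out labels
  become imbalanced; the explainer tree then needs the class-proportion-aware
  reading its per-node probabilities provide (consider K:1 with larger K).
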