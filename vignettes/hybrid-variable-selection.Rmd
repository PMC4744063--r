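---
title: "Hybrid variable selection for complex surveys with missing data: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hybrid variable selection: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(hybridsel)
```

`hybridsel` selects predictors of a binary outcome from a wide panel of
correlated candidates measured in a complex-survey epidemiological study with
missing cells. This vignette is the package's own account of the statistics
it implements: the models and their assumptions, the tunable parameters with
their defaults and rationale, what the synthetic-data generator does and does
not emulate, the numerical choices, and the places where the design was
genuinely open and a decision had to be made.

## The data model

A `survey_dataset` holds an n-by-p numeric value table (outcome, predictors,
covariates), a boolean observation mask (the mask is authoritative; missing
cells are stored as `NA`), per-variable metadata (`kind`:
continuous/binary; `role`), and the design columns: positive survey weights,
stratum labels, and primary sampling unit (PSU) labels nested in strata.
Absent design columns default to a simple random sample (unit weights, one
stratum, one PSU per record). The design degrees of freedom — the reference
for all design-based t and F inference — are `#PSUs − #strata`, which must be
at least 1.

Record-level exclusions follow the common epidemiological workflow: records
with at least `max_missing` missing predictor cells are removed first, then
(optionally) records containing a value beyond k = 8 robust standard
deviations of its column (median ± k·MAD/0.6745). The outlier rule exists to
stabilise imputation in heavy-tailed biomarker panels; it is off by default
because no universal criterion is defensible, and k = 8 is deliberately
conservative — it should fire only on values that would visibly distort a
regression.

## Step 1 — missingness diagnostics and chained imputation

**Diagnostics.** For each predictor with missing cells, a missing-data
indicator (1 = missing) is regressed on the outcome with the same
design-based logistic machinery used everywhere else; a significant
association means missingness is outcome-dependent, so complete-case analysis
would be biased and imputation is warranted. These tests run on the original,
pre-imputation data — running a missingness diagnostic on imputed data would
be circular. Little's MCAR test complements them: the mean μ and covariance
Σ of the predictor panel are estimated by EM under multivariate normality
(binary 0/1 columns are treated as numeric, which is the test's standard
large-panel usage), records are grouped by missingness pattern j, and

d² = Σⱼ nⱼ (ȳⱼ − μ̂ⱼ)ᵀ Σ̂ⱼ⁻¹ (ȳⱼ − μ̂ⱼ),  df = Σⱼ pⱼ − p,

restricted to each pattern's observed coordinates, is referred to the
chi-squared upper tail. EM initialises from complete-case moments
(available-case moments if fewer than 10 complete cases), declares
convergence when the relative observed-data log-likelihood change falls below
1e-8 (cap 500 iterations), and asserts at every iteration that the
log-likelihood has not decreased. Singular pattern sub-blocks are inverted
with a small ridge and a warning.

**Chained imputation.** Missing cells are filled by fully conditional
specification: initialise each incomplete variable with random draws from its
observed marginal; visit variables in ascending missing-count order (the
variables easiest to impute stabilise the early cycles); regress each on all
other imputation predictors using currently-completed values; draw model
parameters from their approximate posterior; draw imputations from the
predictive distribution. Continuous variables use the conjugate
normal–inverse-gamma draw (σ² from a scaled inverse chi-squared on the
residual sum of squares, coefficients normal around the least-squares fit);
binary variables use a logistic maximum-likelihood fit plus a normal
coefficient draw from the estimated covariance, then Bernoulli draws. The
parameter draws are what make the imputation *proper*: without them Rubin's
rules underestimate the between-imputation variance.

Defaults: `m = 20` imputations and `burn_in = 10` cycles per chain. Twenty
imputations sit at the upper end of the 5–20 range considered adequate when
missing fractions are modest, and the diagnostics below showed chains
settling well before ten cycles in all generator settings. A ridge of 1e-5 on
the conditional-model normal equations guards near-collinear biomarker
panels. Chains can be run separately within the levels of a fully observed
grouping variable (e.g. sex) via `group_by`; levels with fewer than 30 rows
are rejected rather than imputed from hopelessly little data.

Two open choices and how they were made. The imputation models exclude the
survey weights and the outcome by default: the applied study this methodology
follows imputed its biomarkers from the other biomarkers plus demographics
only. Both choices are configurable through `predictors`, and the outcome
exclusion matters: if missingness in a predictor is driven by the outcome,
outcome-excluded imputation attenuates that predictor's association (its
imputed cells carry no outcome information). Users who see strong
missing-indicator associations with the outcome should add the outcome to the
imputation predictor set; the package default stays faithful to the source
workflow.

Convergence is monitored through per-cycle traces of imputed-value means and
SDs; a variable is flagged when the range of its last three cycle means
exceeds 0.2 pooled SDs. One honest limitation: because each conditional model
is fitted on the originally-observed rows, chains reach their stationary
means essentially within one cycle under MCAR and observed-driver MAR, so the
trace diagnostic has little transient to display in well-specified settings —
it earns its keep on pathological inputs, and the test suite exercises it on
a synthetically drifting trace.

**Stacking.** The original dataset (set index 0) and the m completed copies
(1..m) concatenate into a long table of n·(m+1) rows with a `_mi_id` column —
the convention that the combined analysis table includes the original set.

## Step 2 — boosted-tree importance and the inclusion rule

The screen is a from-scratch implementation of stochastic gradient boosting
for Bernoulli loss. Starting from the training log-odds F₀, each iteration
computes residuals r = y − p on the training rows, draws a bag of
⌈bag_fraction · n_train⌉ rows *without replacement*, grows a regression tree
on the bag's residuals, replaces each leaf value with the Newton step
γ = Σ r / Σ p(1−p) (denominator floored at 1e-8), and updates
F ← F + λ·tree(x). Trees grow best-first: the leaf whose best split most
reduces the residual sum of squares is split next, with thresholds at
midpoints between adjacent distinct observed values and ties broken toward
the lowest variable index, then the smallest threshold, then the
earliest-created leaf. Rows missing the candidate split variable are excluded
from that split's improvement computation and routed to the child with more
observed rows — the simplest defensible handling, and the reason the screen
can run on the original (incomplete) dataset as well as the completed copies.

Stopping follows the validation rule: rows are split
`train_fraction` : (1 − train_fraction) (default 60:40), and training stops
at the first iteration that fails to improve the validation Bernoulli
log-likelihood, keeping the trees through the best iteration. Strict
first-non-improvement is noisy — at moderate shrinkage the very first tree
occasionally fails to improve the validation fold, leaving a zero-tree
(constant) model — so a `patience` parameter (default 0, the strict rule)
lets pipelines tolerate a few non-improving iterations; 5 is a sensible
pipeline value. Defaults: shrinkage λ = 0.001 (the value the source workflow
settled on; smaller λ needs more iterations, which is why `max_iterations`
defaults to 10,000), 50% bagging, `max_terminal_nodes = 5`,
`min_node_size = 10` (guards degenerate Newton denominators). The terminal-
node default follows the source's stated "six" for "terminal nodes plus 1"
read literally; the parameter is exposed because that phrasing conflicts
with common boosting conventions and other readings are defensible.

Variable importance is the per-variable sum, over retained trees, of the
squared-error improvements of its splits, divided by the number of retained
trees and rescaled to total exactly 100. The screen runs one boosted model
per dataset (original + each imputation, with per-dataset seeds derived from
the master seed) and applies the inclusion rule: a variable is kept if its
importance in the original dataset is *strictly greater than* the cutoff, or
its mean importance across imputations is *at least* the cutoff. The
asymmetry is deliberate and preserved from the source rule. The default
cutoff of 2% was chosen there, against a 67-variable panel (uniform share
1.5%), to keep more than half the total importance; with much smaller panels
the uniform share exceeds 2% and the rule is intentionally inclusive — the
downstream survey screen, not the cutoff, does the pruning. The cutoff is a
parameter, not a constant.

On strongly collinear pairs, boosting usually concentrates importance on one
member: once one variable's signal is absorbed, its twin has little residual
signal left. This is the property that makes the screen preferable to
stepwise selection under collinearity. It is, however, a *usually*: when the
two empirical signals tie almost exactly, shrunk updates alternate between
the twins from the first iterations and the final shares come out balanced.
In repeated simulations with an exactly equal-beta collinear pair
(r = 0.8), the smaller/larger importance ratio fell at or below 0.8 in
roughly three quarters to 85% of runs depending on configuration — and an
independent gradient-boosting implementation showed the same rate — so the
downgrade should be read as a strong tendency, not a guarantee.

## Step 3 — design-based confirmation

**Survey logistic regression.** Coefficients maximise the weighted Bernoulli
pseudo-likelihood (IRLS, score tolerance 1e-10, cap 100 iterations;
|β| > 15 is declared separation and raised as an error naming the term). The
covariance is the Taylor-linearization sandwich: per-record score
contributions wᵢ(yᵢ − pᵢ)xᵢ are totalled within PSUs, centered within
strata, and combined with the n_h/(n_h − 1) small-sample factor — the
with-replacement first-stage approximation, no finite-population correction,
matching how national examination surveys document their designs. Inference
uses t on the design df. Strata with a single PSU are a hard error by
default (variance is not estimable); an optional remedy merges them into one
collapsed stratum, with a message. Subpopulations (the train/validation
halves, analysed as domains) zero the score contributions outside the domain
while keeping every PSU in the variance — standard domain estimation, so a
split never distorts the design. With unit weights and a degenerate design
the whole stack collapses to textbook logistic regression (asserted to 1e-8
in the tests).

**Rubin pooling.** Per term across m completed-data fits: Q̄ = mean
coefficient, W = mean squared SE, B = between-imputation variance,
T = W + (1 + 1/m)B, with Barnard–Rubin degrees of freedom computed against
the complete-data df, which for survey data is the design df (exposed as a
parameter). One point worth writing down: with the Barnard–Rubin adjustment
the pooled df approaches the classical large-sample value (m − 1)(1 + 1/r)²
only as the complete-data df grows; at a fixed small design df, increasing
B/W drives the pooled df toward zero, not toward the classical value. The
tests assert the correct limit.

**Screening and elimination.** Participants are split once, stratified on
the outcome so both halves keep the study prevalence (and the same ids fall
in the same half of every completed copy). Each candidate is screened by a
pooled univariate survey fit in each half and kept if pooled p ≤ α in both
halves; the boundary counts as significant (α defaults to 0.05, uncorrected
— the screen is deliberately permissive, and a Bonferroni variant would
change the method being implemented). Collinearity: pairs with pooled
weighted |r| ≥ 0.95 are flagged and the lower-importance member dropped,
transitively for cliques; 0.95 sits safely above the background correlations
the generator emulates and below the near-singular pairs the rule exists to
break (the motivating example pair had r = 0.968). Mediation: X is declared
fully mediated by M when X is significant univariately, X loses significance
in the joint model {X, M} while M remains significant, and X and M are
associated (|r| ≥ 0.3 or cross-regression p ≤ α); mediated variables are
dropped, and a circular pair (each apparently mediated by the other) is
flagged for review rather than resolved silently. These are operational
criteria for a relationship the source asserts without defining; they are
not causal claims.

**Final model and selection.** The retained biomarkers plus covariates form
the base model; candidate covariate-by-biomarker interactions are screened
one at a time and retained at pooled p ≤ α; the joint model is refitted with
the retained interactions (dropping the weakest on non-convergence, logged).
The method's *selection* is the biomarkers still significant in this joint
confounder-adjusted model — the final stage is itself a filter, which is
what lets the pipeline discard candidates whose marginal association was
entirely borrowed from correlated true predictors. Model adequacy uses the
design-adjusted goodness-of-fit test: g weighted quantile groups of
predicted probability (g = 10 by default), the vector of the first g − 1
group mean residuals tested with a linearized Wald statistic converted to
F(g − 1, design df − g + 2). Under 15 strata and 31 PSUs that is F(9, 8) —
the df structure is asserted exactly in the tests, and its type-I error is
calibrated by simulation.

**Baselines.** Backward stepwise logistic regression (iid ML, remove the
highest-p term while p > α) is included because its failure under
collinearity is part of the method's justification. The L1 baseline fits the
glmnet logistic lasso path per dataset on a 60:40 split, picks the penalty
minimising held-out deviance, and counts selections across the m + 1
datasets — a selection-frequency importance measure.

## The synthetic-data generator

`generate_survey_study` draws correlated standard-normal predictors (pairwise
background correlations Uniform(0.05, 0.30) unless a full matrix is given —
the declared stand-in for the modest correlations seen in real biomarker
panels), a binary outcome from a sparse logistic model with the intercept
solved by root finding to hit a target prevalence (default 0.077, a
realistic depression prevalence), PSU-level normal random intercepts (SD 0.2
on the logit scale) inducing within-cluster correlation, a stratified
design (default 15 strata × 2 PSUs), and log-normal weights with a chosen
coefficient of variation (default 0.5). `generate_collinear_sim` is the
validation scenario: n = 5,227 simple-random records, six predictors with
corr(X₁, X₂) = 0.8, and either equal betas (all 0.3) or varying betas
(0.5, 0.4, 0.3, 0.2, 0.1, 0.05) — the beta values are declared defaults, not
reconstructions of anyone's unpublished settings, with the intercept at −1.
`inject_missingness` deletes cells MCAR, or MAR with deletion probability a
logistic function of a fully observed driver (unit slope per driver SD, the
intercept calibrated by root finding so the marginal fraction is exact in
expectation); outcome and design columns are never deleted.

What the generator does **not** emulate: real biomarker marginals (skewness,
detection limits, heaping), MNAR mechanisms, multistage sampling below the
PSU, calibration/raking of weights, or item-level instrument scoring. Tests
that pass on this generator therefore certify the statistical machinery —
calibration of the tests, recovery under the stated mechanisms, design-df
arithmetic — not robustness to everything field data can do.

## Problem sizes used in the checks

The test suite runs the statistical property checks at sizes chosen to give
each assertion real power while keeping the suite practical to run: Little's
test type-I at n = 300, p = 4 over 200 replicates; goodness-of-fit type-I at
n = 800 over 200 replicates (cluster SD 0 there, since the claim is about a
correctly specified model); CI coverage at n = 1,200 over 300 replicates;
the collinear-pair contrast at the scenario's full n = 5,227 over 50 seeds
with shrinkage raised to 0.01 under a 400-iteration budget (fewer, stronger
steps fit the same signal as the 0.001-shrinkage long run); and the
end-to-end pipeline at n = 3,000 with 30 predictors (3 true, betas 0.9,
0.7, 0.6, prevalence 0.15), 20% MCAR, m = 5 over 20 seeds. Monte-Carlo
replicate seeds are fixed, so every reported rate is reproducible.

## Known limitations

- Only continuous and binary variables are modelled; categorical covariates
  enter as user-constructed dummies (reference rows are added to the final
  table via `reference_levels`).
- The mediation rule is pairwise; a predictor whose association is spread
  over several mediators is caught only by the final-model significance
  filter, not labelled as mediated.
- Little's test assumes multivariate normality; with heavily non-normal
  panels its level is approximate.
- The boosted screen's collinear downgrade is a strong tendency, not a
  guarantee (see Step 2).
- Variance estimation offers Taylor linearization only — no replicate
  weights, no finite-population corrections, no second-stage variance.
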