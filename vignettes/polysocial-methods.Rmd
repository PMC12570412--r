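---
title: "Polysocial scores: models, choices and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Polysocial scores: models, choices and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette is the package's own account of the science it implements: the
models and procedures, the assumptions behind them, the tunable parameters,
and the places where the design was genuinely open and a choice had to be
made.

## The problem

Disability in activities of daily living (ADL) among older adults is shaped
by many social conditions at once — wealth, housing quality, education,
social engagement, religious participation, access to technology and
healthcare. Modelling these factors one at a time ignores their joint,
cumulative structure. A *polysocial score* compresses a participant's whole
social environment into one integer by (i) selecting the factors that carry
predictive signal for the outcome, (ii) weighting each factor level by its
regression coefficient, and (iii) summing. The package implements the full
construction and validation pipeline, gender-stratified and
sampling-weighted throughout.

## Stage 1: ranking by information gain

`rank_factors()` fits a gradient-boosted tree ensemble with the DART booster
(each new tree is fitted after randomly dropping a subset of the existing
trees, which regularises the additive expansion) and ranks factors by total
information gain — the cumulative training-loss reduction attributed to
splits on each factor.

Factors enter the trees as integer level codes, one column per factor, so
gain aggregates per factor without one-hot fragmentation; for the mostly
ordinal factors in this domain (frequencies, counts, quintiles) the codes
also preserve their ordering. The boosting hyperparameters are fixed and
documented in `default_boost_params()`: 100 rounds, learning rate 0.1,
depth-4 trees, dropout rate 0.1, histogram split finding, one thread. They
were chosen once as conventional values for tabular data of a few thousand
rows and are not tuned per dataset; the ranking, not the classifier's raw
accuracy, is the product of this stage. Sampling weights are passed as
instance weights (disable with `use_weights = FALSE` for oracle checks).

## Stage 2: forward selection gated by DeLong tests

`sequential_select()` evaluates nested models with the top-*k* factors.
Model quality is measured by cross-validated AUC: the same stratified
5-fold assignment is reused for every *k*, and each participant is scored by
the model not trained on them. Out-of-fold (rather than resubstitution)
scores are used for the tests because resubstitution AUC increases
mechanically with every added factor.

The paired DeLong test compares model *k* with model *k−1* on these score
vectors. `auc_with_covariance()` implements the structural-components
estimator: the placement of an event is the (weight-)proportion of
non-events it out-scores, ties counting one half; AUC is the weighted mean
placement and the variance combines the event-side and non-event-side
placement covariances. Under sampling weights, covariances are
weight-averaged and normalised by Kish effective sample sizes; with equal
weights the estimator reduces exactly to the classical one (the tests verify
bit-level agreement with an independent implementation).

The stopping rule: maintain a counter of consecutive additions with
`p >= alpha`; stop scanning when the counter reaches two; report the *k*
with the highest AUC among the scanned models. Boundary semantics follow the
standard convention — an addition is an improvement when `p < alpha` — so
`alpha = 0` makes every test a non-improvement and scanning stops after the
first two comparisons, while `alpha = 1` scans the whole ranking. With fewer
than three ranked factors no stopping rule can operate; all factors are
evaluated and the trace is flagged.

## Stage 3: the score card

`fit_weighted_logistic()` fits the outcome on the selected factors by
weighted maximum likelihood (a quasibinomial `glm`), with HC0 sandwich
standard errors whenever weights are non-constant. The point rule is
`points = round(|beta| * 10)`, rounding half away from zero — the rule's own
worked conversions (0.61 × 10 → 6, 0.26 × 10 → 3) pin down nearest-integer
rounding and rule out truncation. Reference levels score 0, and points are
invariant to intercept shifts.

The absolute value makes the rule incoherent for genuinely risk-increasing
levels: they would *add* points despite representing disadvantage. Two modes
are provided. The default pipeline calls `orient_catalog()` first, which
re-levels each factor so its reference is the level with the highest
weighted outcome prevalence; protective coefficients are then negative by
construction and higher scores consistently denote better social conditions.
A literal mode keeps the declared references and `build_scorecard()` warns
about any positive coefficient it scores. Neither mode is asserted to be
the only defensible reading; the warning makes the choice visible.

Score categories use quintiles: low (quintile 1), intermediate (quintiles
2–4), high (quintile 5). Cutpoints are unweighted type-7 quantiles at 0.2
and 0.8 on the analysis sample, with left-closed intervals (a score equal to
a cutpoint moves up, so tied scores always share a category). Fixed integer
cutoff bands (e.g. 0–37 / 38–63 / 64+) are supported for applying a
published card. Whether quantiles should be weighted is genuinely open; the
unweighted default keeps the published-card use-case exact and the choice is
recorded in the output metadata.

## Stage 4: association and validation

`lowess_curve()` smooths the binary outcome on the score (tricube local
linear fits, span 2/3, 3 robustness iterations — conventional settings, as
the method reference prescribes none) to inspect the shape of the relation.
`estimate_ors()` reports odds ratios per one-point increment and across
categories, crude and adjusted for age group, smoking, drinking and sleep
trouble, with Wald CIs on the log-odds scale and sandwich SEs under
weighting (a design choice; likelihood-ratio intervals would also be
defensible but do not pair naturally with design-based variances).

`evaluate_models()` compares the covariate-only reference model with
reference + continuous score and reference + categorical score, all by
ten-fold cross-validated out-of-fold prediction:

* **Discrimination** — C-statistic per model and the paired DeLong delta
  against the reference, computed on the pooled out-of-fold vectors.
* **Calibration** — Hosmer–Lemeshow on deciles of predicted risk (pooled
  out-of-fold), statistic `sum (O-E)^2 / (n p (1-p))`, df = groups − 2;
  degenerate bins are merged with a neighbour rather than dividing by zero.
* **Reclassification** — NRI against the reference model. The category-free
  (continuous) variant is the default because no risk-category thresholds
  are part of the method's definition; a categorical variant is available.
  CIs are percentile bootstrap over participants (paired predictions),
  1000 replicates by default, seeded.

Inside `crossval_predictions()` the design matrix is built once on the full
stratum so that a factor level unseen in some training fold aliases to a
zero column (treated as reference) instead of breaking prediction — a
small-sample robustness choice that leaves full-rank fits untouched.

## The synthetic cohort generator

`simulate_cohort()` emulates the *structural* features the pipeline relies
on, not any real joint distribution:

* ~5,000 participants, 37% men; age strata 60–69 / 70–79 / 80+ with
  population shares 0.662 / 0.258 / 0.080, the two older strata oversampled
  ×2 and ×3 and carrying compensating weights (1/inflation, rescaled to
  mean 1);
* 29 categorical factors in five social-determinant domains
  (`default_catalog()`), with level marginals drawn once per configuration
  from a Dirichlet(4, ..., 4) and stored in the configuration;
* outcome drawn from a logistic model: intercept + per-level factor effects
  + covariate effects (age, gender, smoking, drinking, sleep trouble). When
  no intercept is supplied it is calibrated by root finding so the marginal
  prevalence equals the 18.9% target;
* item missingness applied after outcome generation, MAR by default (cell
  rates depend on age group and gender only, so chained-equation imputation
  assumptions hold by construction); the default cell rate 0.0062 yields
  ~16.5% incomplete rows across 29 factors, matching the design's
  complete-case exclusion fraction.

The *alternative* preset gives eight factors graded protective log-odds
between −0.3 and −1.2 — the magnitude range implied by published per-level
cards whose points run up to about 10 — and leaves 21 factors as noise; the
*null* preset zeroes all factor effects. These presets define the study
conditions for the behavioural tests (signal factors out-rank noise;
selection keeps at least the signal block under the alternative and stops
almost immediately under the null) and were fixed at design time.

Randomness is organised as one master seed with a derived substream per
column (and per pipeline stage), so adding a factor never perturbs the draws
of earlier columns — the practical reproducibility property a per-participant
counter scheme would buy, implemented with ordinary R RNG machinery.

What the generator does **not** emulate: correlation between factors,
informative missingness in the outcome, cluster sampling (weights enter as
inverse selection probabilities only), or any real-world marginal. Passing
tests therefore demonstrate that the machinery is correct under its stated
assumptions, not that any particular substantive finding generalises.

## Imputation sensitivity

`mice_impute()` is a chained-equations imputer for categorical columns:
each target column is modelled by multinomial logistic regression on gender,
age group, the outcome and the other factor columns (entered as integer
level codes — a parsimonious conditional model that keeps ~30 predictors
tractable), fitted on originally observed rows, with missing cells replaced
by categorical draws; the column cycle repeats `iterations` times (default
10) and `m` datasets (default 10) come from independent substreams. Observed
cells are never modified. `pooled_selection()` applies a majority-vote rule
across the imputed datasets — a factor counts as selected when chosen in
more than m/2 of them — and `selection_overlap()` reports the agreement with
the complete-case run as intersection count and Jaccard index.

## Numerical and testing notes

* Sizes used by the test suite: exactness oracles run at n ≤ 40 (exhaustive
  pair counting, hand-summed calibration, leave-one-out); coefficient
  recovery at n = 20,000; selection behaviour at n = 5,000 over 10 seeds;
  the discrimination/reclassification pattern at n = 3,000 over 20 seeds;
  calibration size over 500 replicates at n = 500. These sizes were chosen
  to keep Monte-Carlo error well inside the tested tolerances.
* `weighted_table_one()` uses a first-order design-effect correction: the
  weighted contingency table is rescaled to the Kish effective sample size
  before the Pearson chi-square. This is the simplest Rao–Scott-style
  adjustment; a full second-order correction would need cluster information
  the cohort schema does not carry.
* Perfect separation and rank deficiency in the logistic stage are reported
  as errors naming the offending terms, not silently fitted; levels
  unobserved in one outcome class are flagged as warnings.
* All reported p-values are two-sided at the conventional 0.05 level; the
  selection gate's `alpha` is overridable in `pipeline_config()`.

## Known limitations

* The DeLong gate tests nested models on correlated out-of-fold scores;
  its type-I behaviour as a *sequential* procedure is not formally
  calibrated (the two-consecutive-failures rule is a heuristic guard).
* The |β|×10 rule discards coefficient uncertainty; two levels with very
  different standard errors can earn the same points.
* Under strong factor–factor correlation (not simulated here), gain
  ranking splits credit across correlated factors and the forward order
  can be unstable.
* The weighted variance estimators treat weights as inverse selection
  probabilities under independent sampling; clustered or calibrated designs
  need replication-based variances the package does not provide.
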