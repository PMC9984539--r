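---
title: "Multi-omic plasma biomarker construction: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-omic plasma biomarker construction: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plasmapanel)
```

This vignette is the package's own account of the statistical machinery it
implements: the models and their assumptions, the tunable parameters and why
their defaults are what they are, what the synthetic-cohort generator does
and does not emulate, and the numerical and design decisions taken where the
underlying analysis recipe leaves room.

## The analysis chain

The package implements a biomarker-construction chain for case–control
plasma studies with three omic layers. In the motivating clinical setting
the cases are cavernous angioma (CA) patients — and, within patients, those
with a symptomatic hemorrhage in the prior year (CASH) — but nothing in the
code is specific to that disease.

1. Metabolite peak tables are **ratio-normalized** per sample.
2. Differential features are found by **PLS-DA with permutation
   significance** and BH-FDR.
3. An independent validation cohort is assembled by **propensity-score
   nearest-neighbor matching** on four clinical covariates.
4. Metabolite–protein **Pearson correlations** are screened at |r| > 0.5,
   q < 0.05.
5. Candidate panels are fit by **ridge-penalized logistic regression**,
   evaluated by leave-one-out and stratified 10-fold cross-validation, and
   ranked by the **Youden index** (primary) and an **AIC** on the
   cross-validated error (parallel).
6. Published fixed coefficient combinations are evaluated as-is via their
   **canonical values** (linear predictors).
7. Enriched-pathway sets from different omic layers are **cross-referenced**
   through file-based Fisher-exact enrichment.

## Differential discovery: PLS-DA with permutation significance

PLS1 components are extracted by NIPALS from the autoscaled (centered,
unit-variance) feature matrix against the centered class indicator
(case = 1, control = 0). The reported per-feature statistic is the
regression coefficient of the class on the autoscaled features implied by
the retained components; with as many components as features this reduces
exactly to ordinary least squares, which is the oracle the test suite uses.

Significance is assessed by refitting under `B` random permutations of the
class labels and, for feature *j*, the two-sided add-one estimator

p_j = (1 + #{b : |β_j(b)| ≥ |β_j|}) / (B + 1),

followed by Benjamini–Hochberg FDR across features. Label permutation is
the exchangeability-valid reading of "random permutations analysis";
permuting the peak values of each feature independently would break the
feature correlation structure and invalidate the null.

Assumptions and caveats:

* Autoscaling before PLS-DA is the package's choice (standard for
  intensity tables of widely different scales); the analysis recipe this
  implements does not state a scaling.
* `n_components` defaults to 2 and is exposed; the coefficient statistic is
  fairly insensitive to this for the small cohorts targeted here.
* The permutation test on PLS-DA coefficients is honest but conservative at
  small n with many features: informative features share a component, so
  each one's coefficient is diluted, and in a 20 + 20 cohort with hundreds
  of peaks the BH-corrected screen can legitimately come back empty while
  the panel search still recovers the signal. This is visible in the
  package's own tests and is a property of the method, not a defect.
* `B` defaults to 999 and must be at least 100; the attainable minimum p is
  1/(B+1), so with 200 features and B = 999 a single feature can never
  reach q < 0.05 alone — a point to remember when choosing B.

## Preprocessing rules

**Ratio normalization.** "Plasma ratio levels" are implemented as each
feature divided by its sample's total observed signal (rows sum to 1 over
non-missing cells). The recipe never defines the normalization; this
total-signal reading matches the "ratio" phrasing and standard untargeted-MS
practice. The operation is idempotent, and missing cells stay missing.

**Duplicate wells** are averaged arithmetically; if one member of a pair is
missing the observed value is kept (the recipe is silent; discarding real
measurements seemed worse).

**Outlier exclusion** is per feature and per group: values beyond
`k_sd` standard deviations from the group mean are masked, with `k_sd = 2`
for protein assays and `k_sd = 3` for miRNA relative quantification. Three
conventions are fixed deliberately:

* *single pass* — the mean and SD are computed once on the original values,
  with no re-exclusion after masking (whether the original rule was
  iterative is unstated; single-pass is the conservative reading);
* *strict inequality* — a value exactly at mean + k·SD is retained;
* *n−1 SD*. A consequence worth knowing: a lone extreme point in a group of
  n can reach at most (n−1)/√n SDs from the single-pass mean, so the ±2 SD
  rule cannot fire in groups smaller than 6 and the ±3 SD rule in groups
  smaller than 11. Groups below 3 observed values are skipped and reported.

**Endogenous-control choice and ΔCq.** Candidate control miRNAs are ranked
by a simplified NormFinder-style stability score
s = √(Var(group means) + mean within-group variance), computed on Cq with
the n−1 variance convention (fixed by the package's worked example:
group means {20, 22} with zero within-group variance give s = √2). The
winner normalizes the layer as ΔCq = Cq(miRNA) − Cq(control); the output
stays on the ΔCq scale (lower = more abundant) rather than 2^−ΔCq, since
downstream models are linear and the monotone transform only changes
coefficient units; the sign convention is recorded in the table's units
tag.

## Propensity matching

A logistic model of case status on age, sex, phenotype and brainstem lesion
supplies the scores (the matching software used originally is named but not
its model; logistic propensity is the standard reading). Complete
separation falls back to the package's own ridge-stabilized logistic
(ridge = 1e−4) with a warning. Matching is greedy one-to-one single nearest
neighbor without replacement or caliper: cases in descending score order,
ties broken by smallest control id, so results are deterministic.

Greedy matching is *not* the optimal assignment: on random instances with
up to six per class its total score distance equals the brute-force optimum
only roughly 60% of the time (the acceptance measurements report the rate).
That gap is inherent to the greedy rule, which is retained because it is
the procedure being modeled; an optimal-assignment mode was deliberately
left out of scope.

Per-covariate balance improvement is also a *sample-size* property: with
only 20 cases, a binary covariate's pre-matching standardized mean
difference is occasionally near zero by chance and no matching method can
improve on it, so the package's balance checks use 40-case cohorts with a
4:1 control reservoir and strong confounding (log-OR 1.5 per covariate),
where matching reliably shrinks all four SMDs. At 20 cases, expect
"all four improved" in only ~80–85% of cohorts.

## Correlation screen

Pearson r on pairwise-complete samples; two-sided p from
t = r·√((n−2)/(1−r²)) with n−2 df; one BH pass over the full metabolite ×
protein grid; screen at |r| > 0.5 *and* q < 0.05, both strict. Pairs with
fewer than 4 complete observations are skipped with a reason; |r| = 1 is
flagged degenerate and reported with the smallest representable p rather
than 0. At n ≤ 7 the exhaustive permutation distribution of r is a step
function with jumps of order 1/n!, so t-based and permutation p agree
closely in the strong-correlation regime the screen targets but can differ
by more than 0.05 on a few percent of configurations — the acceptance
measurements quantify this rather than asserting a universal bound.

## Ridge-penalized logistic panels

The classifier is P(X) = e^{Xβ}/(e^{Xβ}+1) with coefficients minimizing the
penalized Bernoulli negative log-likelihood

L(β) = −Σ [Y ln p + (1−Y) ln(1−p)] + ridge·‖β‖²,

with the intercept unpenalized and ridge = 1e−8 by default. The printed
form of this loss in the source recipe, with "(1−Y)(1 − ln p)" in place of
"(1−Y) ln(1−p)", is unbounded below along any separating direction and so
cannot be a likelihood; it is treated as a typographical slip, and a unit
test evaluates both forms to document the divergence.

Optimization is a damped Newton iteration (exact penalized Hessian,
step-halving) from zero initialization, gradient tolerance 1e−6, at most
500 iterations, with a BFGS fallback if a Newton step is unusable. At the
default near-zero ridge on separable data the minimizer lies at very large
but finite ‖β‖; the fit then stops at the iteration cap with
`converged = FALSE` flagged on the result rather than raising — by design,
since such fits still classify perfectly. Missing cells are mean-imputed,
and in every cross-validation fold the imputation means are recomputed from
the training fold only, so no information leaks from held-out samples.

**Cross-validation.** LOOCV is the primary scheme; stratified 10-fold
(seed-reproducible folds; k reduced to the minor class size with a warning
when needed) runs in parallel. In each fold a Youden threshold is derived
from the *training-fold* canonical values and applied to the held-out
canonical values; sensitivity, specificity, accuracy, AUC and MAE
(mean |p̂ − Y|) are computed from held-out predictions only.

**Model selection.** Candidate subsets (exhaustive up to `max_m`, default
4; otherwise a CFS-seeded greedy path) are ranked primarily by held-out
Youden J with ties broken toward fewer features and then higher sensitivity
(a small sensitive panel being the clinical preference), and in parallel by

AIC = n·ln(MAE₁₀₋fold) + 2(m + 1),

an adopted formula: the recipe names the two ingredients (cross-validated
MAE, compound count) but no functional form, so printed AIC values from the
original study are *not* reproduction targets — only the ranking behavior
is. CFS uses the classic merit k·r̄_cf / √(k + k(k−1)·r̄_ff) with absolute
Pearson correlations and stops when no addition improves it.

**Fixed models.** The four published weighted combinations ship as JSON
coefficient files (`packaged_model()`), with per-term units recorded;
feature names suffixed `_r` take ratio-normalized or ΔCq-relative levels,
unsuffixed protein names take absolute concentrations. Their canonical
values are plain linear predictors, so a zero feature vector returns the
published intercept — the package's arithmetic check.

## Pathway cross-referencing

Enrichment is file-driven: a GMT annotation defines pathways and the
background universe (live database queries are out of scope). Per pathway,
the one-sided Fisher exact p is the hypergeometric upper tail; BH runs
across pathways; and "Bayes factor > 3" — undefined in the source recipe —
is implemented as the Sellke–Bayarri–Berger minimum Bayes factor
1/(−e·p·ln p) (for p < 1/e, else 1), a reproducible, assumption-light
surrogate with the threshold exposed. Enriched sets from different layers
are intersected with pairwise-overlap counts.

## The synthetic-cohort generator

`generate_cohort()` emulates the data structure the chain assumes:

* **Abundances** (metabolites, proteins) are log-normal; group effects are
  additive on the log scale with standardized size `effect_size`
  (informative features alternate sign). Peak intensities are positive and
  right-skewed, which is exactly what this produces.
* **Case assignment is confounded**: a logistic model on age (Normal(45,12)
  truncated to [18, 85]), sex, phenotype and brainstem lesion (0/1) sets
  latent utilities, and the top-`n_case` utilities become cases, so group
  sizes are exact while covariates still shift case probability — giving
  propensity matching real confounding to remove.
* **miRNA Cq** values are Normal(25, 2)-scale cycle numbers; informative
  miRNAs shift Cq downward in cases (lower Cq = more abundant); two
  endogenous-control candidates have 8× and 5× smaller SD than targets so
  the stability ranking is well-defined; a spike-in column is constant up
  to 0.05-cycle pipetting noise.
* **Missingness** is independent per cell at `missing_rate`; **outliers**
  are displaced to mean + 8 within-group SD, at most one per feature-group,
  which keeps abundances positive and guarantees the single-pass ±2 SD rule
  flags every injected cell in groups of ≥ 8. Everything injected is
  recorded in `truth`.
* The default configuration (20 + 20 samples, 200 metabolite peaks with 4
  informative, 4 proteins with 2 informative, 8 target miRNAs with 3
  informative, d = 1.5, unit log-scale noise) mirrors a small matched
  validation cohort; the original study reports no effect-size estimates,
  so d is a free parameter chosen once as a moderate, realistic signal.

What it does **not** emulate — and hence what green tests do *not*
establish about real data: raw spectra and peak detection, retention-time
drift and batch effects, heteroscedastic or intensity-dependent missingness
(missingness here is completely at random, whereas real MS missingness is
left-censored), correlated metabolite modules beyond one planted
metabolite–protein factor, heavy-tailed measurement error, or plate effects
in qPCR.

## Problem sizes of the shipped checks

The test suite and `scripts/acceptance.R` exercise the chain at the scales
the methods are meant for, chosen as the package's own benchmark sizes:
null calibration on 40 + 40 cohorts with 200 peaks and B = 999; ridge
oracle comparisons on n = 20 two-feature fits against an iteratively
refined grid search; ROC/Youden oracle equality on instances with n ≤ 12;
panel recovery over 50 simulated 40 + 40 cohorts with 3 of 12 features
informative at d = 1.5 (exhaustive subsets ≤ 4, 10-fold AIC ranking);
matching balance over 50 confounded 40/160 cohorts; and an end-to-end
pipeline determinism audit on a 20 + 20 cohort with B = 199. The full suite
runs in a few minutes on one CPU.

## Known limitations

* PLS-DA permutation p-values share one set of permutations across
  features; p-values are therefore dependent across features (BH remains
  valid under the usual positive-dependence conditions).
* The greedy matcher's optimality gap and the small-sample behavior of
  per-covariate balance are described above; both are properties of the
  modeled procedure.
* The AIC form and the "Bayes > 3" surrogate are the package's documented
  interpretations of under-specified steps; results depending on their
  exact values should be read accordingly.
* Exhaustive panel search grows as C(pool, ≤ max_m); beyond `max_m = 6` or
  pools of a few dozen features, use the CFS-seeded greedy strategy.
* `ridge_logistic()` fits small panels (the intended use); it is not a
  high-dimensional solver.
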