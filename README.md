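# plasmapanel

Construction and evaluation of weighted-combination diagnostic biomarkers
from plasma multi-omic measurements — metabolite peak intensities, protein
concentrations and miRNA qPCR Cq values — as used in cavernous angioma (CA)
biomarker studies, where the clinical question is distinguishing CA patients
from healthy subjects and, among patients, identifying those with a recent
symptomatic hemorrhage (CASH).

The package is aimed at biomarker developers who have sample × feature
tables per omic layer plus clinical metadata, and who want the full
analysis chain as reproducible, tested code:

1. **Differential discovery** — PLS-DA (NIPALS) of the class on
   ratio-normalized feature tables; per-feature coefficient significance by
   label permutation, `p_j = (1 + #{b : |β_j^(b)| ≥ |β_j|}) / (B + 1)`;
   Benjamini–Hochberg FDR; z-score matrices for heatmaps.
2. **Propensity matching** — logistic propensity on age, sex, phenotype
   (sporadic/familial) and brainstem lesion; greedy one-to-one single
   nearest-neighbor pairing without replacement; covariate-balance report.
3. **Association screen** — Pearson correlation of metabolite and protein
   levels, `t = r·√((n−2)/(1−r²))` with n−2 df, pooled BH correction,
   screen at |r| > 0.5 and q < 0.05.
4. **Preprocessing** — per-sample total-signal ("ratio") normalization,
   duplicate-well averaging, single-pass ±k·SD per-group outlier exclusion
   (±2 SD proteins, ±3 SD miRNA), endogenous-control stability ranking and
   ΔCq = Cq(miRNA) − Cq(control) relative expression.
5. **Biomarker models** — ridge-penalized logistic regression
   (`P(X) = e^{Xβ}/(e^{Xβ}+1)`, Bernoulli negative log-likelihood +
   ridge·‖β‖², default ridge = 1e−8, damped-Newton fit), leave-one-out and
   stratified 10-fold cross-validation with in-fold Youden thresholds and
   imputation, Youden-index and AIC = n·ln(MAE) + 2(m+1) model selection,
   CFS feature screening, exhaustive/greedy panel search, and evaluation of
   the published fixed coefficient combinations shipped as JSON files.
6. **Pathway cross-referencing** — file-based (GMT) Fisher-exact enrichment
   with BH FDR and a minimum-Bayes-factor screen (`1/(−e·p·ln p)`), and
   intersection of enriched pathway sets across omic layers.
7. **Synthetic cohorts** — a generator emulating the study's data structure
   (log-normal abundances, covariate-confounded case assignment, Cq layers
   with control columns, missingness, gross outliers) with full truth
   bookkeeping, so every stage is testable without patient data.

## Worked example

```r
library(plasmapanel)

# simulate a 40 + 40 discovery-style cohort: 60 metabolite peaks, 4 of them
# shifted by d = 2 on the log scale between cases and controls
coh <- generate_cohort(cohort_config(n_case = 40, n_control = 40,
                                     n_metabolites = 60, effect_size = 2,
                                     seed = 42))

# differential metabolites by PLS-DA + label permutation + BH
dt <- differential_analysis(log(unclass(coh$metabolites)), coh$metadata,
                            B = 999, seed = 1)
head(dt[order(dt$p_perm), ], 6)
#>  feature_id coefficient p_perm  q_bh    direction selected excluded
#>      met001      0.1376  0.001 0.020   up_in_case     TRUE    FALSE
#>      met002     -0.1351  0.001 0.020 down_in_case     TRUE    FALSE
#>      met003      0.1238  0.001 0.020   up_in_case     TRUE    FALSE
#>      met004     -0.1072  0.007 0.105 down_in_case    FALSE    FALSE
#>      met032      0.0480  0.312 0.995   up_in_case    FALSE    FALSE
#>      met043      0.0453  0.396 0.995   up_in_case    FALSE    FALSE
```

Three of the four planted metabolites clear the q < 0.05 screen (the
coefficient sign gives the direction; met004's signal is diluted at this
seed). A cross-validated panel search over six candidates then ranks
subsets by held-out Youden J and by AIC:

```r
x <- log(unclass(coh$metabolites))[, paste0("met00", 1:6)]
sr <- search_panels(x, coh$metadata$group, max_m = 3, seed = 1)
sr$best_by_youden
#>              features m loocv_sensitivity loocv_specificity loocv_accuracy
#>  met001+met002+met003 3             0.975                 1          0.988
#>  loocv_auc youden_J kfold_sensitivity kfold_specificity kfold_mae  aic
#>          1    0.975             0.975                 1  0.000291 -643

# published fixed-model arithmetic: zero metabolite levels return the
# printed intercept
fam <- packaged_model("familial_metabolite")
canonical_values(fam, matrix(0, 1, 1,
                 dimnames = list("s", "decanoyl-L-carnitine")))
#>     s
#> -0.37
```

The LOOCV sensitivity/specificity are computed from held-out predictions
only, with the classification threshold re-derived inside each training
fold by the Youden scan.

The whole chain runs from one config:

```r
cfg <- run_config(simulate = cohort_config(seed = 7), B = 999, seed = 7)
run_pipeline(cfg, "run7")   # cohort/, differential_table.tsv,
                            # matched_pairs.tsv, correlations.tsv,
                            # panel_search_log.tsv, fixed_model.json,
                            # manifest.json, run.log
```

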