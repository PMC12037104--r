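# metadrift

Concept drift analysis for metabolomic classifiers: detect the confounding
factors that silently degrade phenotype prediction, and correct for them.

## The problem

Classifiers that predict a phenotype (sex, disease status) from a shared
panel of 20-30 metabolite abundances are haunted by **confounding
factors** -- covariates such as age, BMI or creatinine that change the
relationship between metabolites and label but are absent from the model's
inputs. Averaged test accuracy hides the damage: the model is accurate on
the cohort's majority stratum and quietly wrong on the rest.

`metadrift` turns this into a **concept drift** detection problem. The
per-sample misclassification indicators of a fitted model are laid out as a
0/1 stream ordered by a candidate covariate; a confounder then appears as a
change point in the stream's error statistics. Two classic streaming
detectors localise it:

* **DDM** tracks the running error rate `p_i` and its binomial standard
  deviation `s_i = sqrt(p_i (1 - p_i) / i)`, flags a *warning* when
  `p_i + s_i > p_min + 2 s_min` and a *drift* above `3 s_min`, where
  `(p_min, s_min)` is the historical minimum of `p_i + s_i`;
* **EDDM** tracks the distances between consecutive errors, flagging when
  `mean + 2 sd` of the distances falls below 0.95 (warning) / 0.90 (drift)
  of its historical maximum.

The covariate values at the confirmed warning positions nominate the
confounder and a candidate threshold (e.g. "age 26"); the pipeline then
corrects the model either by **segmentation** (one model per stratum) or by
**stratified scaling** (normalization parameters fitted within confounder
strata) and reports paired before/after accuracies and drift counts.

The package also ships the surrounding machinery a practitioner needs:
KEGG-id harmonization, half-minimum imputation, 2-SD outlier screening, the
eight standard metabolomics scaling transforms (centering, autoscaling,
pareto, range, vast, level, log10, power), a seeded five-family classifier
suite (kNN, ridge, thresholded SVR, random forest, feed-forward network),
and a cohort simulator with covariate-dependent concept drift for
validation.

## Worked example

Simulate a 500-sample cohort of 22 metabolites in which the
metabolite-to-sex relationship flips for samples older than 26 years, then
run the full pipeline (Sections A-C) with ridge classification under
autoscaling:

```r
library(metadrift)

cfg <- run_config(
  simulate = sim_config(n_samples = 500),      # true threshold: age 26
  scaling  = list(methods = "autoscaling"),
  classify = list(families = "ridge"),
  correct  = list(auto_accept = TRUE),
  seed     = 2)
run <- run_pipeline(cfg)
#> accepting nominated confounder `age` at threshold 26.38.
run
#> <metadrift_run>
#>   grid: 1 scaling method(s) x 1 classifier family(ies)
#>   nominated confounder: age @ 26.38 (combo autoscaling|ridge)
#>   mean accuracy before 0.860 -> after 0.990; drifts 1 -> 1
run$nomination$scan
#> # A tibble: 2 x 8
#>   covariate n_warnings n_drifts warning_range scaled_range max_elevation
#>   <chr>          <int>    <int>         <dbl>        <dbl>         <dbl>
#> 1 age                1        1             0            0        0.345
#> 2 bmi                1        1             0            0        0.0274
#> # i 2 more variables: candidate_threshold <dbl>, drift_boundary <dbl>
```

Reading the output: on the age-ordered error stream the scan found a
confirmed drift episode whose error rate stays 0.35 above its in-control
reference -- a strong, sustained concept change -- so `age` is nominated,
with the warning-derived threshold 26.4, within half a year of the
simulator's true threshold. The decoy covariate BMI also produced a drift
event (the canonical DDM rule is alarm-prone on clean streams; see the
vignette), but its sustained elevation is only 0.03, so the ranking
dismisses it. After segmenting the cohort at the threshold and retraining
per stratum, test accuracy rises from 0.86 to 0.99; the single remaining
"drift" on the corrected stream is the warm-up false-alarm floor of the
canonical detector discussed in the vignette.

Individual stages are ordinary functions over tibbles and compose with the
pipe: `impute_half_min()`, `screen_outliers()`, `split_dataset()`,
`scale_cohort()`, `train_model()`, `evaluate()`, `build_error_stream()`,
`ddm_detect()`/`eddm_detect()`, `associate_covariate()`,
`derive_threshold()`, `segment_by_threshold()`, `stratified_scale()`.
Results carry `tidy()`/`glance()` methods and `autoplot()` views (error
stream with event markers, grey-scale covariate track, before/after
accuracy comparison).

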