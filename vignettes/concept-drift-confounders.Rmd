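---
title: "Detecting and correcting confounding factors in metabolomic classifiers with concept drift analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting and correcting confounding factors in metabolomic classifiers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Phenotype classifiers built on metabolite abundance panels routinely ingest
20-30 shared metabolites and predict a binary label such as sex or disease
status. Their weak spot is the *confounding factor*: a variable -- age, BMI,
creatinine level -- that changes the relationship between metabolite values
and the label but is not itself among the model's inputs. A model trained on
a cohort dominated by one side of the confounder silently degrades on the
other side, and ordinary test-set accuracy averages the damage away.

`metadrift` treats this as a *concept drift* problem. If the cohort's
misclassification indicators are laid out as an ordered 0/1 stream -- ordered
not by time but by a candidate covariate -- then a change in the
feature-to-label relationship at some covariate value becomes a change in
the stream's error statistics at the corresponding position. Streaming drift
detectors can localise that change, the covariate values at the triggering
positions nominate the confounder and a candidate threshold, and the model
can then be corrected by segmenting the cohort at the threshold or by
fitting the normalization within confounder strata.

The pipeline has three sections:

* **A** -- harmonize the abundance table, scale it, train and evaluate a
  grid of classifiers (kNN, ridge, thresholded SVR, random forest, a small
  feed-forward network) under each of nine normalizations;
* **B** -- build covariate-ordered error streams for the fitted models, run
  the DDM and EDDM detectors, associate warning/drift positions with
  candidate covariates, and nominate a confounder plus threshold;
* **C** -- correct (segmentation or stratified scaling), retrain
  identically, and report paired before/after accuracies and drift counts.

```{r}
library(metadrift)
cfg <- run_config(
  simulate = sim_config(n_samples = 500, seed = 7),
  scaling  = list(methods = c("none", "autoscaling", "pareto")),
  classify = list(families = c("ridge", "random_forest")),
  correct  = list(auto_accept = TRUE),
  seed     = 7)
run <- run_pipeline(cfg)
run$report
```

## Harmonization

Tables from different studies are unified by renaming free-text metabolite
names to KEGG compound identifiers (`map_identifiers()`, with a local
mapping table; two input features mapping onto one compound is treated as an
ambiguity and raised, never merged) and reducing all tables to their common
feature panel in a canonical lexicographic order (`intersect_features()`).

Missing abundances are left-censored in practice, so `impute_half_min()`
replaces each missing entry with half the smallest observed value of that
metabolite (per feature, the field convention). The operation is idempotent
and never touches observed entries.

Outliers are screened per *condition* and per compound: an entry is flagged
when it lies strictly outside two sample standard deviations of its
condition group's mean (`flag_outliers()`; the group defaults to the target
class). The default policy replaces flagged entries with missing values and
re-imputes once. Note that for approximately Gaussian data a 2-SD rule
flags about 4.6% of perfectly sound measurements; `screen_outliers()`
therefore also offers a report-only policy. A subtle interaction matters
later: before the confounder is known, the screen's condition groups mix
both sides of the confounder, so genuinely drifted measurements sit in the
tails of their class distribution and are preferentially flagged. Section C
therefore repeats the screen with condition = class x confounder stratum
once the confounder has been accepted -- after nomination, the stratum *is*
part of the condition.

The train/test split (`split_dataset()`, default 80/20) is stratified by
the target class and reproducible under the configured seed.

## The scaling family

`fit_scaler()` estimates per-feature mean, standard deviation (n-1),
minimum and maximum; `apply_scaler()` applies one of the canonical
transforms:

| method      | definition                          |
|-------------|-------------------------------------|
| centering   | `x - mean`                          |
| autoscaling | `(x - mean) / sd`                   |
| pareto      | `(x - mean) / sqrt(sd)`             |
| range       | `(x - mean) / (max - min)`          |
| vast        | `((x - mean) / sd) * (mean / sd)`   |
| level       | `(x - mean) / mean`                 |
| log10       | `log10(x)`                          |
| power       | `x ^ exponent` (square root default)|

Parameters are estimated on the training split only and applied unchanged
to held-out samples; a fit-on-all mode exists for exploratory use.
Degenerate denominators (constant features, zero means) fall back to plain
centering with a warning rather than producing non-finite values. `log10`
of a non-positive value is a hard error unless the epsilon-offset mode is
explicitly enabled. All affine members are exactly invertible
(`invert_scaler()`), and every member is monotone within feature, so ranks
are preserved.

## Classifiers

The five families are deliberately standard; the package pins small
hyperparameter grids (kNN k in {3, 5, 7}; ridge penalty in {0.1, 1, 10};
200 trees; a 32-16 ReLU network with sigmoid output trained by an
adaptive-moment optimizer for 200 epochs at 1e-3) and resolves any grid
with more than one candidate by stratified cross-validated accuracy
(10 folds by default, reduced when a class is small). Labels are encoded
male = 0 / female = 1 so that the regression-based families (ridge on the
0/1 code, eps-regression SVR) classify by thresholding at 0.5
deterministically. Class imbalance is not re-weighted. Every family is
seeded and reproducible; the network is plain full-batch gradient descent
with Adam moments in double precision, so it is bit-stable on a given
platform.

## Drift detection

`ddm_detect()` implements the classic error-rate monitor: with `i`
instances since the last reset and error rate `p_i`, it tracks
`s_i = sqrt(p_i (1 - p_i) / i)` and the historical minimum of `p_i + s_i`
(components `p_min`, `s_min`). After a 30-instance warm-up it signals a
warning when `p_i + s_i > p_min + 2 s_min` and a drift when
`p_i + s_i > p_min + 3 s_min`, then resets. `eddm_detect()` monitors the
mean and standard deviation of the distances (in instances) between
consecutive errors, tracks the maximum of `mean + 2 sd`, and signals when
the current value falls below 0.95 (warning) or 0.90 (drift) of that
maximum, after 30 observed errors. The comparisons are strict
inequalities: an all-correct stream, where the minimum is exactly zero,
must never alarm. Both detectors emit a coincident warning when a drift
fires in an episode that had none, so a warning opens every drift episode.

Two numerical/behavioural points deserve emphasis.

* *Warning periods can be cancelled.* When the statistic re-enters the
  in-control region, the open warning period was a false alarm; only the
  warning period still active when the drift fires marks the transition's
  onset. The association stage flags exactly those warnings as
  *confirmed*.
* *The zero-minimum warm-up artifact.* If the first 30 instances since a
  reset contain no error, `p_min = s_min = 0` and the next error --
  whenever it arrives -- is an immediate drift. This is inherent to the
  published update rule (it is also what makes the textbook trace "30
  clean instances then one error drifts at index 30" hold) and it sets a
  floor on false alarms for very clean streams: on stationary
  Bernoulli(0.1) streams of length 1000 the canonical rule alarms in
  roughly 40% of streams, dominated by early small-sample races between
  the minimum and the current statistic. The detector is kept canonical;
  consumers of drift *counts* on clean streams should read them with this
  floor in mind, which is also why nomination relies on sustained error
  elevation rather than raw event counts (below).

## Stream construction and scopes

`build_error_stream()` orders the per-sample misclassification indicators
of a fixed fitted model ascending by a candidate covariate (ties broken by
sample id) or leaves them in dataset order. Two scopes are used:

* the *reported* warning/drift counts come from the held-out test stream
  (`drift$stream_scope = "test"`), keeping counts honest about
  generalisation;
* the *nomination scan* runs on the fixed model's predictions over the
  whole cohort (`confounder$scan_scope = "all"`). A 20% test split of a
  ~500-sample cohort leaves only a handful of samples per year of age near
  the threshold, far too sparse to localise the change point; the full
  cohort samples the covariate axis densely. For the high-bias linear
  model that anchors nomination, in-sample errors still expose concept
  mismatch (the model lacks the capacity to absorb it), so the scan stream
  remains informative despite containing training samples.

## Confounder nomination

`associate_covariate()` records, for every event, the covariate value of
the ordered sample at the event position -- the covariate need not be the
ordering key, and it may be a metabolite column re-used as covariate. For
each drift it also measures an *elevation*: the error rate over the 30
instances after the trigger minus the episode's reference level. A false
alarm reverts towards its baseline (elevation near zero); a genuine
transition sustains it.

`derive_threshold()` implements the threshold rules. The default,
`mean_of_warnings` over confirmed warnings, keeps the episodes sustaining
at least half of the maximum elevation and weights each episode's final
warning by its elevation. This matters in practice: the detector's
early-warm-up false episodes otherwise enter the average and drag the
threshold several years low. The plain unweighted mean over all warnings
(`use = "all"`) and the `mean_of_drifts` / `midpoint` rules are available.

`scan_covariates()` (and the pipeline's internal scan) evaluates each
candidate covariate under its own stream ordering and ranks candidates by
the dominant episode's sustained elevation, tie-broken by how tightly the
confirmed warnings cluster in (range-scaled) covariate units. Ranking by
cluster tightness alone is degenerate -- a lone coincident warning from a
false alarm has range zero and would outrank a genuine cluster -- which is
why elevation leads. In the pipeline the scan is pooled across all
drift-positive (scaling x family) combinations: the covariate is chosen by
majority vote and the threshold is the median of the per-combination
estimates, since a genuine confounder surfaces across normalizations while
detection noise does not.

The expert step is preserved: by default `run_pipeline()` asks for
confirmation of the nominated confounder in interactive sessions;
`correct$auto_accept = TRUE` (or a non-interactive session) accepts it
with a message.

## Correction

Two strategies realise the correction:

* **Segmentation** (`segment_by_threshold()`): split the cohort at the
  threshold and train a model per stratum. This is the only strategy that
  can repair a *sign reversal* of the feature-label relationship -- no
  per-stratum affine rescaling can -- but it costs data: each stratum must
  still support training, and the package refuses strata with fewer than
  two samples per class, advising stratified scaling instead.
* **Stratified scaling** (`stratified_scale()`): fit the scaling
  parameters separately within each binary stratum (on training samples)
  and apply them stratum-wise to all splits. No samples are lost and the
  sample order is unchanged. This is exact for *shift-type* confounding
  (stratum-level location offsets), the common case for age- or
  batch-related level changes; it cannot repair sign reversals.

The pipeline's `correct$strategy = "auto"` picks segmentation when every
stratum can support per-stratum training and falls back to stratified
scaling otherwise. After correction, drift detection is re-run with the
same ordering, detector configuration and seeds, and
`compare_before_after()` pairs the runs into a per-(scaling x family)
report with accuracy and event-count deltas; mismatched splits or seeds
refuse to pair.

## The cohort simulator

`generate_cohort()` emulates the statistical structure the analysis
assumes, so the whole pipeline is testable without external downloads:

* a two-class (sex) panel of 22 metabolites with baseline abundances
  uniform on 100-1000 and within-class coefficient of variation 0.15;
* heterogeneous dimorphism: per-feature class separations alternate
  between 1.5 and 0.8 within-class standard deviations. Real panels mix a
  few strongly sex-marked compounds with many weak ones, and the
  heterogeneity is load-bearing: if every feature carried the same effect,
  a multivariate linear model could discard the drifted block (whose
  shared regime factor makes it high-variance) and classify both regimes
  from the clean features alone, making the drift undetectable by any
  error-stream monitor;
* a young-skewed age distribution, `18 + 57 * Beta(1, 9)` (median ~22,
  mean ~24, range 18-75), emulating volunteer/student-recruited healthy
  cohorts; the young majority is what anchors a full-cohort model on the
  below-threshold concept so that error is elevated above the threshold;
* concept drift above a true threshold (default 26 years) on the most
  strongly dimorphic half of the panel -- confounding tracks the very
  metabolites that carry the predictive signal. Modes: `flip`
  (interpolated sign reversal), `attenuate`, `shift` (class-independent
  location offset, the case stratified scaling repairs exactly);
* missing values (2% of cells) and gross outliers (0.5%, at 4 within-class
  standard deviations) injected on top, with coordinates recorded in the
  ground truth.

What it does **not** emulate: inter-feature correlation (configurable
effects are independent given class and regime), instrument batch effects,
longitudinal repeated measures, or non-Gaussian abundance noise. Passing
tests on simulated cohorts therefore demonstrate that the machinery
recovers the structure it assumes, not that any particular real cohort
satisfies those assumptions.

`generate_error_stream()` draws piecewise-Bernoulli 0/1 streams for
detector-level tests.

## Validation and problem sizes

The test suite checks the streaming detectors against independent
from-scratch recomputations on a thousand random streams (lengths
50-2000, error rates 0.01-0.5), verifies every scaling transform against
hand-derived vectors and brute-force recomputation, and runs a
50-replicate end-to-end study (cohorts of 500 samples, 22 features,
concept flip above age 26) measuring threshold recovery and paired
before/after accuracy and drift counts. `scripts/acceptance.R` recomputes
the same quantities from scratch for any seed. The 500-sample, 50-replicate
design keeps the full study within a few minutes on one CPU while leaving
the binomial noise on the reported rates around two percentage points.

## Known limitations

* The canonical DDM false-alarm floor described above means drift *counts*
  on clean, short streams include a substantial stochastic component;
  qualitative "no drift remains" statements should be read against that
  floor.
* Nomination assumes a single dominant binary threshold per covariate;
  gradual or multi-threshold confounding will be localised at best
  approximately.
* Stratified scaling corrects location/scale confounding only; sign
  reversals need segmentation (and hence data).
* The uncorrected upper stratum of a young-skewed cohort is small, so the
  corrected per-stratum model there remains noticeably noisier than the
  lower stratum's -- visible as a residual error step in some replicates.
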