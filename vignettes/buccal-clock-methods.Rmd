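---
title: "Building multi-objective buccal epigenetic clocks with buccalclock"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Building multi-objective buccal epigenetic clocks with buccalclock}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

An epigenetic clock predicts chronological age from CpG methylation levels.
First-generation clocks are trained purely for accuracy (typically penalized
linear regression of age on beta or M values), which makes their *delta age*
— predicted minus chronological age — close to pure noise: it rarely carries
the lifestyle and health signal that makes a clock useful as a biomarker.
`buccalclock` implements a different construction, designed for buccal
(cheek-swab) methylation arrays: linear age models over *CpG clusters* are
searched by simulated annealing under a multi-objective score that rewards
age accuracy **and** the statistical significance of delta-age associations
with lifestyle/health survey responses, while penalizing model complexity.
The top-scoring models are combined into a weighted ensemble with an age-bias
rotation.

Because real buccal cohorts of the relevant scale are proprietary, the
package ships a first-class synthetic-cohort generator with planted age,
lifestyle, replicate and cell-composition structure. Every stage of the
pipeline is exercised and tested against that generator; no external data are
required.

## Pipeline overview

1. **Input** — a probes x samples methylation matrix (beta or M scale), a
   probe manifest (chromosome, position, island relation, genes), and a
   survey table (age, 11 lifestyle/health responses scaled to [0, 1], -1/+1
   binary demographics, categorical and technical covariates, optional
   replicate groups).
2. **Filtering** (`filter_probes()`) — sequential rules in a fixed, reported
   order: exclusion list, detection p-value, missingness, sex chromosomes,
   variance. The report is a partition: removals plus survivors account for
   every input probe.
3. **Clustering** (`cluster_cpgs()`) — hierarchical agglomerative clustering
   of probes with distance 1 − Pearson correlation between profiles, average
   linkage, cut so probes merged above a correlation threshold (default 0.7)
   share a cluster. `select_top_clusters()` ranks by size, then
   within-cluster variance, then id; `average_clusters()` takes per-cluster
   arithmetic means of M values, the unit of model input.
4. **Annealing** (`anneal()`, `train_many()`) — subset search over clusters;
   weights are refit by ordinary least squares at every proposal.
5. **Ensembling** (`build_ensemble()`, `calibrate_rotation()`) — worst-
   anchored linear weighting of the top-scoring models plus an affine
   age-bias rotation fitted on training data only.
6. **Evaluation** (`cross_validate()`, `compute_metrics()`,
   `delta_age_model()`, `baseline_penalized_cv()`) and descriptive analyses
   (`binned_profile()`, `factor_correlation_overlap()`,
   `context_enrichment()`, `differential_variability()`).

## The objective

For a model with cluster subset $S$, OLS weights $w$, prediction
$\hat{a}$ and delta $\delta = \hat{a} - a$:

$$
\mathrm{score}(S) \;=\; w_{\mathrm{rmse}}\,\mathrm{RMSE}(\hat a, a)
\;+\; w_{\mathrm{sig}} \sum_{f} \log_{10} \max\!\big(p_f,\; p_{\mathrm{floor}}\big)
\;+\; w_{\mathrm{cplx}}\,|S|,
$$

lower is better. $p_f$ is the two-sided test of the **partial** Pearson
correlation of $\delta$ with lifestyle factor $f$ **given age**
($t = r\sqrt{n-3}/\sqrt{1-r^2}$).

Two aspects of the significance term deserve justification, because both were
forced by observed failure modes of the more obvious formulation:

* **Age adjustment** (`sig_partial_age = TRUE`). With an unadjusted
  correlation test, a deliberately *inaccurate* clock scores well: its delta
  is essentially $-a$ plus noise, and therefore "significantly correlates"
  with every factor that is itself age-correlated (most self-report factors
  are). On synthetic cohorts the unadjusted objective reproducibly walked
  into that basin (RMSE 13–19 years with enormous significance terms).
  Partialling out age closes the channel exactly while leaving genuine
  lifestyle signal in the prediction untouched. The *reporting* function
  `delta_age_pvalues()` remains a plain univariate correlation test; only
  the in-objective statistic is adjusted.
* **Saturation** (`p_floor`, default 1e-10). Without a floor the term is
  unbounded: sacrificing all accuracy to make delta a noisy copy of one
  factor drives one $p_f$ toward machine zero (hundreds of log10 units),
  which out-buys any RMSE penalty at any useful $w_{\mathrm{sig}}$. With a
  saturation floor each factor can contribute at most
  $-\log_{10} p_{\mathrm{floor}}$ (10 units), so the search earns the reward
  for a clearly significant association but gains nothing further from
  destroying the clock. Elsewhere (reporting, BH input) p-values are floored
  only at 1e-300 to avoid $-\infty$.

With both in place the objective is stable for $w_{\mathrm{sig}}$ anywhere in
0.1–1 on the standard synthetic cohort (RMSE 3.6–9 years, increasing in
$w_{\mathrm{sig}}$). The default is $w_{\mathrm{rmse}} = 1$,
$w_{\mathrm{sig}} = 0.2$, $w_{\mathrm{cplx}} = 0.01$ per cluster, chosen on a
calibration cohort as the largest significance weight that leaves accuracy
essentially unchanged (RMSE ~3.8 vs ~3.2 years at $w_{\mathrm{sig}} = 0$).

## The annealer

Proposals add, drop, or swap one cluster (probabilities 1/3 each), weights
are refit by least squares, and the move is accepted with probability 1 if it
improves the score and $\exp(-\Delta S / T)$ otherwise. The temperature
follows geometric cooling $T \leftarrow cT$ with $c = 0.995$; the initial
temperature is auto-calibrated in a 100-proposal warm-up so that a median
worsening move would be accepted with probability ~0.8. The best model ever
visited is returned, and the full trace (iteration, temperature, current and
best score) is available for audit. All randomness flows from one integer
seed; identical seeds give bit-identical trajectories. Rank-deficient
designs are solved by the minimum-norm pseudo-inverse with a warning.

On universes small enough for exhaustive enumeration (12 clusters, models up
to size 3) the annealer attains the enumerated optimum in ≥ 95% of seeded
repeats — this is asserted in the test suite against an oracle that uses
`lm()` and the textbook partial-correlation identity rather than the
package's own scoring path.

## Ensemble, rotation, cross-validation

Training is repeated (1098 times at production scale; desk-scale runs use
12–100) and the top `top_k` models (default 100) are combined. Weights are
*worst-anchored linear*: $w_i \propto S_{\mathrm{worst}} - S_i + \epsilon$,
normalized to sum to one, so a strictly better score always earns a strictly
larger weight, identical scores give uniform weights, and no extra
temperature parameter is introduced (a softmax alternative would need one).
The ensemble prediction is the weighted mean of member linear predictions —
a convex combination, bounded by the member predictions.

Systematic age bias (slope compression) is corrected by the *rotation*: fit
$\mathrm{raw} = \alpha\,a + \beta$ on training data and report
$(\mathrm{raw} - \beta)/\alpha$. After rotation the training-set MAB is zero
by construction. The rotation is stored inside the serialized clock and
never refit at prediction time, so test labels are never touched.

`cross_validate()` runs tenfold CV with 12-model fold ensembles by default.
Fold assignment operates on replicate groups, not samples, so test–retest
pairs never straddle the train/test boundary — replicate leakage would
deflate exactly the reliability metric (MRE) the harness exists to estimate.

Serialized clocks are versioned JSON; floating-point fields are stored both
as decimals (for reading) and as C99 hexadecimal float literals, a
decimal-free encoding that round-trips IEEE doubles bit-exactly, so a
saved-and-reloaded clock reproduces predictions identically.

## Metrics

* RMSE, MAE — standard error measures in years.
* $R^2$ — squared Pearson correlation of prediction and age.
* MAB (mean absolute bias) — mean absolute deviation of the fitted
  prediction-vs-age line from the identity line; zero exactly when the fit
  is unbiased. Chosen so the rotation drives it to zero on training data.
* MRE (mean replicate error from the mean) — mean absolute deviation of each
  replicate sample's prediction from its replicate group's mean prediction;
  averaged over samples, so a pair differing by $\Delta$ contributes
  $\Delta/2$ per member.

`delta_age_model()` regresses delta age on all lifestyle, demographic,
technical and cell-composition covariates jointly (one-hot encoding with
first-level reference, aliased columns dropped with a warning), with
two-sided t-tests and Benjamini–Hochberg adjustment (`bh_fdr()`, a
validating wrapper over `stats::p.adjust`; the test suite checks it against
a brute-force step-up oracle). `baseline_penalized_cv()` is the
first-generation comparator: per-fold elastic net (`glmnet`), penalty chosen
by inner cross-validation.

## The synthetic generator

`simulate_cohort()` draws ages uniformly on 18–93 years; lifestyle responses
come from a Gaussian copula with configurable age correlations (defaults are
modest, with smoking and stress declining and self-perceived aging rising
with age) mapped to [0, 1]. Probe M values are a sum of cell-mixture
baseline, cluster-level age slope times centred age, lifestyle effect times
centred response, cluster-shared biological noise, a per-probe offset, and
probe-level measurement noise. Two pseudo cell types with
Dirichlet-distributed proportions give the deconvolution step a recoverable
target; chrX/chrY probes with sex-dependent signal give the sex predictor
one. `add_replicates()` duplicates sampled columns with technical noise
(190 pairs at production scale; desk-scale tests use 10–50).

Design choices worth recording:

* **Dual-signal lifestyle clusters.** By default, clusters carrying the
  planted lifestyle effect also carry an age slope, with the effect's sign
  aligned to the slope ("the exposure pushes methylation in the aging
  direction"). This is not incidental: with OLS weight refitting, a
  lifestyle effect on age-orthogonal dedicated clusters can never reach
  delta age — such clusters get near-zero weight, and in-sample residuals
  are exactly orthogonal to included cluster averages. Lifestyle signal
  reaches delta age only by riding on age-informative clusters, which is
  also the biologically plausible route, and sign alignment prevents leaks
  from different clusters cancelling in an ensemble. Accuracy-only training
  treats the lifestyle component as noise and prefers pure age clusters;
  the significance term prefers the dual clusters — that contrast is what
  the mechanism test asserts.
* **Uniform ages** avoid confounding the bias (MAB/rotation) checks with
  cohort age structure.
* **Noise split** into cluster-shared and probe-level components lets tests
  dial within-cluster correlation independently of cluster signal: with
  probe noise zero, cluster recovery is exact (adjusted Rand index 1) as
  long as no shared age slope genuinely merges clusters, which is why the
  recovery test plants none.

What the generator does *not* emulate: array chemistry (intensities, dye
bias, probe type I/II differences), realistic manifest annotation (island
relations are drawn independently of signal), cohort-shaped age densities,
and correlated missingness. Passing tests therefore demonstrate that the
algorithms recover planted structure under the stated noise model, not that
the clock generalizes to real arrays.

## Problem sizes and numerical choices

The standard benchmark cohort is 500 subjects, 300 clusters of 1–8 probes
(20 age-linked at 0.02–0.05 M/year, 5 lifestyle-linked at 3 M per unit
response), cluster noise SD 0.4 M, probe noise SD 0.25 M, 50 replicate
pairs; tenfold CV with 12-model fold ensembles and 2000 annealing iterations
per model. On one CPU this runs in about four minutes and reaches
out-of-fold $R^2 \approx 0.98$, far above the 0.8 the package asserts, so
the margin absorbs unlucky seeds. M-value conversion clips betas at 1e-3 by
default (a recorded configuration value, so results are reproducible);
beta↔M composition is identity to 1e-12 on the clipped interval. Equal-width
age bins (default 15) are used for trajectory profiles; equal-count binning
is a config alternative. The differential-variability statistic is a
two-sided F-test — simplest for two groups, exactly calibrated under
normality; Levene-type alternatives can be substituted upstream of the BH
step. Fisher's exact test (not chi-square) backs context enrichment so that
small-count categories remain exact.

## Known limitations

* The clustering step computes a full probe-probe correlation matrix;
  beyond ~50k probes it needs chunking, which is not implemented — filter
  first.
* The significance term uses univariate (age-adjusted) tests, not the full
  multivariate covariate model; the final evaluation (`delta_age_model()`)
  is where covariates are held constant.
* The sex predictor and cell-type deconvolution consume matrices, not
  intensities; they are contracts over methylation summaries, not
  re-implementations of array-level tooling.
* `p_floor` and the objective weights are calibrated at desk scale
  (n ≈ 500); a cohort two orders of magnitude larger would warrant
  re-calibration, since log10 p magnitudes scale with n.
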