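---
title: "Spatial TAM metrics and optimism-corrected survival modelling: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spatial TAM metrics and optimism-corrected survival modelling: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tamspatial)
library(survival)
```

This vignette documents the statistical methods implemented in
`tamspatial`, the assumptions behind them, the tunable parameters, and
the design decisions taken where several defensible choices existed. It
states no empirical result that the test suite or the acceptance script
does not itself compute.

## 1. Data model

The unit of observation is a tissue-microarray core: a 600 µm-diameter
circular sample of tumor, represented as a table of segmented cells
with centroid coordinates (µm), a compartment call (`cancer` vs
`stromal`, taken as authoritative from upstream segmentation), and a
CD163 mean intensity (arbitrary units, non-negative). Clinical data are
one row per patient: PFS time in months, progression indicator, and
covariates (age, race, grade, nodal status, tumor size category,
hormone-receptor and Her2 status, radiation, hormone-therapy
compliance). Hormone-receptor status and compliance are combined into
one three-level factor (`HR+ compliant` reference, `HR+ non-compliant`,
`HR-`), because compliance is undefined for HR− disease.

Two cohort-level rules run before any analysis, in a fixed order forced
by their dependencies: cores with fewer than 10 cancer cells are
excluded (the background tolerance limit below needs a minimal
background sample); then, after phenotyping, patients with duplicated
cores keep the core with the higher CD163+ TAM count (ties broken by
the lexicographically smallest core id, for determinism).

## 2. Background-referenced TAM phenotyping

Cancer cells do not express CD163, so their measured CD163 signal in a
core is an internal estimate of that core's background noise —
including any core-specific staining variation. The positivity
threshold is a one-sided non-parametric upper tolerance limit on this
background: the smallest ascending order-statistic rank $r$ of the $n$
background intensities such that

$$P\{\mathrm{Binomial}(n, p) \le r - 1\} \ge \gamma,$$

with content $p = 0.95$ and confidence $\gamma = 0.99$. The event on
the left is exactly "the $r$-th order statistic exceeds the population
$p$-quantile", so the rule guarantees that, with 99% confidence, at
least 95% of the background distribution lies below the threshold —
with no distributional assumption. A stromal cell is a CD163+ TAM iff
its intensity is *strictly* above the threshold ("above" is read
strictly; ties have measure zero for continuous intensities).

Two non-obvious choices:

* **Exact rule vs published table.** Published tolerance-limit tables
  with interpolation on $n$ are supported (`utl_spec(mode = "table")`,
  with linear interpolation and rounding to the nearest integer rank),
  but the default is the exact binomial rule: it is self-contained,
  reproducible, and exact at every $n$.
* **Small-sample degeneracy.** For $p = 0.95,\ \gamma = 0.99$ the
  nominal confidence is unattainable below $n = 90$; cores may have as
  few as 10 cancer cells. The implementation then uses the sample
  maximum and flags the result `degenerate`, reporting the achieved
  confidence $1 - p^n$ (0.40 at $n = 10$). This is the only
  conservative option: any smaller rank has even lower coverage.

## 3. The seven spatial metrics

Cells form a multitype marked point pattern (cancer / CD163+ TAM /
CD163− stromal). Per core:

| metric | definition | default parameters |
|---|---|---|
| `tam_count` | CD163+ TAMs in the sampled core area | 0.28 mm² (600 µm disc) |
| `tam_proportion` | TAMs / all stromal cells | — |
| `nnd_p10`, `nnd_p25`, `nnd_p50` | percentiles of the per-cancer-cell distance to the nearest TAM | truncation 600 µm |
| `adj_mean` | mean TAMs strictly within 12 µm of a cancer cell | 12 µm ≈ one cell diameter (juxtacrine range) |
| `comm_mean` | mean TAMs strictly within 250 µm of a cancer cell | 250 µm ≈ maximal paracrine signalling distance |

Numerical conventions, chosen once and applied everywhere:

* Percentiles use linear interpolation between order statistics (type-7
  quantiles), the default convention of this statistical environment —
  this matters on small cores where quartiles fall between order
  statistics.
* Distances are capped at the 600 µm truncation before summarizing.
  Inside a valid 600 µm window the cap is a no-op; its real role is the
  zero-TAM convention: a core with no CD163+ TAMs (a real and retained
  phenotype) reports all count metrics 0 and all NND percentiles
  exactly 600.
* Both disc radii use strict `<`.
* No edge correction is applied to distances or disc counts. The
  metrics are defined on the observed pattern of a small fixed window;
  per-cell counts near the boundary are attenuated for every core
  alike, and the downstream analysis only uses between-core contrasts.
* All metrics are invariant under translation, rotation and reflection
  of the coordinates, and the NND/disc computations agree with
  brute-force all-pairs enumeration to 1e-9 (both properties are
  tested).

## 4. Data-driven dichotomization

Candidate thresholds for a metric are midpoints between consecutive
unique observed values whose two groups each hold at least `min_leaf`
(default 7) observations; no split is attempted below `min_split`
(default 20) observations. The selected split maximizes the
standardized two-sample log-rank statistic in score form: with
log-rank scores $a_i = \delta_i - \hat\Lambda(t_i)$ (Nelson–Aalen), the
statistic for threshold $c$ is

$$z^2(c) = \frac{\left(\sum_{x_i \le c} a_i\right)^2}
                {\frac{n_1 n_2}{n(n-1)} \sum_i a_i^2},$$

the maximally-selected log-rank construction. A survival-tree tool
with an exponential-deviance splitting criterion selects near-identical
first splits; the log-rank form was chosen because it is transparent
and directly checkable against an independent per-candidate scan
(tested, including against an independent survival-tree implementation
on a toy example).

The split is *retained* only if it survives 10-fold cross-validation:
within each training fold the best split is re-derived, a two-rate
exponential model is fitted on the training side, and its held-out
predictive deviance is summed; the split is kept iff the one-split
model class beats the no-split model. Re-deriving the split per fold is
essential — fixing the full-data split and cross-validating only the
rates leaks the selection into every held-out fold and retains most
null splits. (Rates use a $(d + 0.5)/T$ stabilizer so folds with an
eventless side stay finite.)

The reported cutpoint is the median of the retained splits across 1000
bootstrap resamples; its 90% CI is the 5th/95th percentile of that
distribution. Resamples retaining no split are excluded from the
quantiles and counted (`n_failed`) — the handling of such replicates is
not specified by the motivating methodology, and exclusion is the
choice that keeps the cutoff distribution interpretable. Dichotomized
markers are `high` iff strictly above the cutoff; for metrics whose
risk direction is inverted (the NND percentiles — *short* distances are
the risky side) a direction field swaps the reported contrast
("low vs high") rather than silently re-signing estimates.

The combined marker collapses two dichotomized metrics into three risk
categories: (1) low communicating-TAM count and high median NND
(reference), (2) low count and low median NND, (3) high count with any
median NND.

## 5. Optimism-corrected Cox modelling

Cox models use Efron tie handling throughout (the data are reported to
0.001 months; ties are rare but must be handled deterministically).
Proportional hazards are checked per term by the scaled-Schoenfeld
score test at $\alpha = 0.05$; violating covariates move into model
strata (continuous covariates are binned into quartiles first). The
"parsimonious" covariate preset is grade + combined HR/hormone-therapy
factor + nodal status + size category; the "full" preset adds age, race
and radiation.

Deriving a cutpoint and estimating its hazard ratio on the same data
inflates the apparent effect. The bootstrap optimism correction: for
each of $B = 500$ resamples, re-derive the cutpoint, fit the Cox model
in the resample ("bootstrap performance") and on the original data
("test performance") at that cutpoint; optimism is the mean difference
of the coefficient vectors, and the corrected estimate is the apparent
coefficient minus mean optimism. Confidence intervals use the apparent
standard errors around the corrected estimate.

Inside the correction the cutpoint rule is the maximally selected split
*without* the cross-validated retention step. Under the null the
CV-pruned tree usually (correctly) retains nothing, which would leave
the "apparent" marker undefined in most datasets — the correction must
mirror a rule that always produces a marker, and it is precisely the
always-split rule whose optimism needs removing. Replicates with no
candidate split or a degenerate fit are skipped and counted, with a
warning above 20%.

### Missing covariates

Covariates are multiply imputed (default $m = 40$) by chained
equations: logistic models for binary variables, multinomial for
unordered factors, proportional-odds for ordered factors, Bayesian
linear regression for continuous ones, cycling 10 sweeps from a
random-draw initialization. Following standard survival-imputation
practice, every imputation model includes the event indicator and the
Nelson–Aalen cumulative-hazard transform of the follow-up time as
predictors (the outcome must be complete; only covariates may be
missing). The optimism-correction algorithm runs independently within
each completed dataset and the corrected coefficients are pooled by
Rubin's rule — pooled estimate $\bar q$, total variance
$\bar u + (1 + 1/m) b$, with the $(m-1)(1 + \bar u/((1+1/m)b))^2$
degrees-of-freedom adjustment. Pooling the corrected estimates (rather
than pooling optimism itself) follows the stated order of the procedure
being reproduced; the two orderings are algebraically close.

## 6. The synthetic-data generator

No public dataset accompanies the motivating study, so the generator is
a first-class, tested module encoding the statistical structure the
analysis assumes:

* **Geometry.** Cancer cells from a parent–offspring cluster process
  (5 parents, 40 µm offspring dispersion) mimicking tumor nests;
  CD163− stromal cells uniform in the 600 µm disc; true TAMs placed
  uniformly, *attracted* (Gaussian displacement, default sd 30 µm, from
  a random cancer cell, rejection-sampled into the window) or
  *repulsed* (uniform conditioned on above-median distance to the
  nearest cancer cell).
* **Intensities.** Lognormal background (meanlog 0, sdlog 0.5) for
  cancer and CD163− cells; true TAMs shifted by +2.0 on the log scale
  (four background log-sds) — separated enough for reliable
  phenotyping, overlapping enough that classification is non-trivial.
* **Cohorts.** Default 400 patients; per-patient TAM fraction uniform
  on (0.02, 0.35) to create realistic between-patient spread; per-core
  defaults 150 cancer / 300 stromal cells. Survival from an exponential
  baseline with hazard multiplier
  $\exp\{\beta\,1[\text{metric} > c] + x'\eta\}$ on the designated
  metric (default `comm_mean`, true $\beta = \log 3$); the true
  threshold $c$ defaults to the realized cohort median of the metric
  (returned in the ground-truth record). The baseline rate is
  calibrated in closed form against uniform (6, 120)-month censoring to
  hit a target event fraction of 0.60. Covariate frequencies mimic a
  chemotherapy-treated breast-cancer cohort; effects are moderate
  (log HRs 0.3–0.6). Missingness is MAR through a logistic model on the
  always-observed age, at 2–3% for most covariates and 15% for the
  hormone-therapy factor (this variable is the one with substantially
  higher missingness in practice; rates far above that would make small
  synthetic fits unstable rather than more realistic).
* **Leakage control.** True TAM labels and the (cutpoint, β) record
  travel outside the cell/clinical tables; the file writer emits only
  the canonical columns, and a test asserts the pipeline inputs carry
  no ground truth.

What the generator does *not* emulate: staining batch effects and
spatial intensity gradients, segmentation errors, cell-size variation,
non-exponential baseline hazards (a Weibull alternative would be a
one-line change in the time draw), and informative censoring. Passing
tests therefore demonstrate the *statistical machinery* — coverage of
the UTL, recovery of cutpoints and threshold effects, removal of
dichotomization bias — under the generator's idealized conditions, not
robustness to imaging artefacts.

## 7. Problem sizes used in the checks

The simulation-based checks run at the scales the methodology itself
prescribes: cutpoint recovery on 100 cohorts of n = 400 with B = 1000
bootstrap cutpoints; null-bias removal on 200 cohorts of n = 300 with
B = 200; end-to-end effect recovery on 50 cohorts of n = 400 with
B = 200 and m = 5. Unit-level property tests use smaller cores
(60 cancer / 120 stromal cells) where the property under test is
size-free; phenotyping-fidelity checks use the default core size, since
classifier sensitivity depends on the background sample size. The UTL
Monte-Carlo uses 10,000 replicates at n = 200, with the usual
3-binomial-SE allowance when comparing an empirical proportion against
its nominal bound.

## 8. Known limitations

* The UTL treats the cancer compartment as pure background; CD163
  spillover from adjacent stained cells into cancer-cell masks raises
  the threshold and makes calling conservative.
* One core per patient: within-tumor heterogeneity is not modelled, and
  metrics from a 0.28 mm² sample are noisy estimates of the tumor-level
  quantity.
* The optimism correction addresses cutpoint-selection bias, not model
  misspecification; covariate effects are corrected with the same
  machinery but their optimism is small by comparison.
* The multinomial/proportional-odds imputation draws use fitted
  category probabilities without a parameter-uncertainty draw (the
  binary and continuous engines do draw parameters); with the default
  m = 40 this slightly understates between-imputation variance for
  multi-category covariates.
* `fisher_exact_rxc` falls back to a seeded Monte-Carlo p-value on
  tables too large for exact enumeration and records that it did so.
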