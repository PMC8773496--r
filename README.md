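# tamspatial

Spatial metrics of interaction between CD163+ tumor-associated
macrophages (TAMs) and cancer cells, with honest survival modelling of
the resulting biomarkers.

## The problem

M2-like (CD163+) macrophages suppress anti-tumor immunity, and their
density in the tumor stroma is associated with poor prognosis in breast
cancer. Classical assessment — a pathologist visually counting stained
cells — is laborious, subjective, and blind to *where* the macrophages
sit relative to the cancer cells, even though TAMs act on cancer cells
through short-range juxtacrine contact and longer-range paracrine
signalling. `tamspatial` implements an objective, operator-independent
pipeline from segmented immunofluorescence tissue-core images (one row
per cell: centroid coordinates, cancer/stromal compartment, CD163
intensity) to optimism-corrected hazard ratios for progression-free
survival (PFS):

1. **Phenotyping.** The CD163 signal of the *cancer* cells in a core is
   background noise (cancer cells do not express CD163). Each core's
   positivity threshold is the non-parametric upper tolerance limit
   (UTL) of that background: the smallest order statistic `r` of the
   `n` background intensities such that
   `P(Binomial(n, p) <= r - 1) >= gamma`, with content `p = 0.95` and
   confidence `gamma = 0.99`. A stromal cell is a CD163+ TAM iff its
   intensity is strictly above the UTL.
2. **Spatial metrics.** The cells form a multitype marked point pattern
   (cancer / CD163+ TAM / CD163− stromal) in a 600 µm circular core
   (sampled area 0.28 mm²). Seven per-core metrics: TAM count, TAM
   proportion among stromal cells, the 10th/25th/50th percentiles of the
   cancer-to-nearest-TAM distance distribution (NND, truncated at
   600 µm; zero-TAM cores score 600), and the mean number of *adjacent*
   (< 12 µm) and *communicating* (< 250 µm) TAMs per cancer cell.
3. **Dichotomization.** Each metric's cutpoint is the median of 1000
   bootstrap survival-tree first splits (maximally selected log-rank
   statistic with 10-fold cross-validated retention); the 5th/95th
   bootstrap percentiles give its 90% CI.
4. **Honest effect sizes.** Deriving a cutpoint and estimating its
   hazard ratio on the same data is optimistic. The bootstrap optimism
   correction re-derives the cutpoint in each of 500 resamples, fits the
   Cox model in the resample and in the original data, and subtracts the
   mean difference of log hazard ratios from the apparent estimate.
   Missing covariates are multiply imputed by chained equations (40
   datasets) and results pooled by Rubin's rule; proportional-hazards
   violations are handled by stratification.

Because the motivating study's clinical cohort is not public, the
package ships a first-class synthetic-data module
(`generate_core()`, `generate_cohort()`) that emulates the study's data
structure — clustered cancer-cell nests, proximity-controlled TAM
placement, background-plus-shift lognormal intensities, Cox survival
with a known threshold effect, MAR covariate missingness — so every
stage is testable against known ground truth.

## Worked example

```r
library(tamspatial)
library(survival)

cohort <- generate_cohort(cohort_gen_spec(n_patients = 200), seed = 42)
ph      <- phenotype_cores(cohort$cores)          # per-core UTL + TAM labels
metrics <- compute_metrics(ph$cores)              # the seven spatial metrics
d <- merge(metrics,
           cohort$clinical[c("patient_id", "pfs_months", "progressed",
                             "grade", "node", "size_cat", "hrht")],
           by = "patient_id")

fit <- otcox(Surv(pfs_months, progressed) ~ grade + node + size_cat + hrht,
             data = d, marker = "comm_mean",
             B_cutpoint = 500, B_optimism = 200, m = 10, seed = 7)
fit
#> Optimism-corrected Cox model with data-driven dichotomization
#>   n = 200 , events = 125 ; imputations m = 10
#>   comm_mean: cutpoint 30.45 (90% CI 17.93-46.33)
#>   strata: grade
#>   bias-adjusted marker effect(s):
#>                   term   hr ci_lower ci_upper       p
#>  High vs low comm_mean 1.85     1.23     2.77 0.00289
```

Reading the output: the communicating-TAM metric was dichotomized at
30.4 TAMs per cancer cell (the median of 500 bootstrap survival-tree
splits; this synthetic cohort was generated with a true threshold at
40.2 and a true hazard ratio of 3). `grade` failed the
proportional-hazards score test and was moved into the model strata.
The reported HR 1.85 (95% CI 1.23–2.77) is the *bias-adjusted* effect:
the apparent log HR (0.78) minus the mean optimism estimated from 200
bootstrap re-derivations of the cutpoint, pooled across 10 imputed
datasets — at this small n the correction and cutpoint noise pull the
estimate well below the apparent one, which is exactly the point.
`summary(fit)` shows all covariate rows; `plot(fit)` draws the
Kaplan–Meier curves by marker group; `predict(fit, newdata)` assigns
risk groups.

The same analysis runs end-to-end from delimited files (cell table +
clinical table) with `run_pipeline()`, which also emits the metric /
association / hazard-ratio tables and a JSON manifest of seeds and
exclusions.

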