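# hubdrs

Interictal MEG network hubs, surgical resections, and post-operative
seizure freedom.

## What this package does

In drug-refractory focal epilepsy, one network-level hypothesis is that
strongly connected regions ("hubs") of the interictal functional brain
network drive seizures, so that resections which capture hub regions should
more often leave the patient seizure-free. `hubdrs` implements the complete
analysis pipeline for testing this hypothesis on source-localized MEG
region-of-interest (ROI) time series, plus a synthetic-cohort generator
that makes every stage testable end-to-end without patient data.

The pipeline:

- **Sliding-window connectivity** — Pearson (amplitude) correlation
  matrices over 2-s windows with 50% overlap, averaged element-wise into
  one functional network per one-minute epoch; up to three epochs per
  recording, separated by at least five minutes.
- **Intra-hemispheric node strength** — the mean correlation of each region
  with all other regions of its hemisphere; inter-hemispheric entries are
  masked with `NA`.
- **Resection labeling** — removed/spared labels from an explicit region
  list or from a parcellation label volume plus binary resection mask
  (NIfTI), with the any-overlap rule: one overlapping voxel marks a region
  removed.
- **D_RS** — Distinguishability of Removed vs Spared node strength: the
  normalized Mann-Whitney U over all removed x spared pairs
  (ties get half credit),

      D_RS = [ #{(r,s): S_s > S_r} + 0.5 #ties ] / (n_R n_S)

  0 = every removed node stronger than every spared node, 0.5 =
  indistinguishable, 1 = the reverse.
- **Group inference** — outcome discrimination of D_RS: AUC with a
  logit-transformed Hanley–McNeil 95% confidence interval and a one-tailed
  rank-sum test (seizure-free patients hypothesized to have lower D_RS);
  duration analyses: robust bisquare regression of mean connectivity on
  log10 epilepsy duration per segment, and a random-intercept
  (per-segment) linear mixed model pooled across segments, both judged by
  likelihood-ratio tests.
- **Synthetic cohorts** — a hub-structured Gaussian factor model with
  closed-form population correlations, planted hub-removal/outcome coupling
  and a planted duration–connectivity association, fully reproducible from
  one seed.

## Worked example

```r
library(hubdrs)

cfg <- run_config(cohort = cohort_config(record_minutes = 10 / 60, seed = 7))
res <- run_pipeline(cfg)

res$stats$segments$segment_1$outcome
#> AUC = 0.83, 95%CI = 0.61-0.94 (n = 12 vs 19), one-tailed rank-sum p = 0.00134 [normal_approx]

res$stats$segments$segment_1$duration
#> robust_ols: slope = 0.009305 (SE 0.000594), LRT p = 1.95e-16, adjusted R2 = 0.909

head(res$table, 3)
#>   subject_id segment       drs   mean_fc outcome duration_years
#> 1    sub-001       1 0.3443396 0.1215874   ILAE1      38.396534
#> 2    sub-002       1 0.2087264 0.1122964   ILAE1       4.337226
#> 3    sub-003       1 0.2676887 0.1056343   ILAE1       1.532339
```

Here the planted effect (90% of the resected hemisphere's hubs removed in
seizure-free subjects vs 10% otherwise) is recovered as an AUC well above
0.5 with a small one-tailed p, and the planted loading-scale growth with
log10 duration appears as a positive robust-regression slope. Individual
worked values: `drs_from_strengths(c(4, 5), c(1, 2, 3))` is `0` (all
removed nodes stronger), identical strengths give `0.5`, and
`auc_logit_ci(0.76, 12, 19)` gives the interval `(0.54, 0.90)` after
rounding to two decimals.

A real analysis replaces the simulated cohort with per-epoch ROI matrices
(`read_timeseries_csv()` or any regions x samples matrix plus a sampling
rate), an atlas table (`read_atlas()`), and resection labels
(`label_from_list()` or `label_from_nifti()`), then calls the same
`epoch_mean_fc()`, `intra_hemispheric_strength()`, `drs_statistic()` and
`group_stats()` chain.

See the vignette (`vignettes/hub-removal-and-outcome.Rmd`) for the model,
its assumptions, and every numerical design decision.

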