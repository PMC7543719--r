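---
title: "Network hubs, resections and D_RS: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Network hubs, resections and D_RS: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hubdrs)
```

## The scientific question

In drug-refractory focal epilepsy, surgery aims to remove the tissue that
generates seizures. A long-standing network hypothesis holds that strongly
connected regions — *hubs* — of the interictal (between-seizure) functional
network are disproportionately involved in seizure generation, so that
patients whose resections capture hub regions should more often become
seizure-free. `hubdrs` implements the full analysis chain needed to test
this on source-localized MEG region-of-interest (ROI) time series:

1. **Connectivity.** For each one-minute epoch, Pearson correlation matrices
   are computed over a 2-second sliding window with 50% overlap and averaged
   element-wise into a single epoch network.
2. **Node strength.** Each region's strength is its mean correlation with
   all other regions *of the same hemisphere*. Inter-hemispheric entries are
   masked (set to `NA`, never zero) because unilateral resections make
   within-hemisphere contrast the informative part.
3. **Resection labels.** Regions are labeled removed or spared from either a
   surgical report list or a parcellation volume plus binary resection mask,
   with the any-overlap rule: a single overlapping voxel marks a region
   removed.
4. **D_RS.** The distinguishability of removed vs spared node strengths:
   the normalized Mann-Whitney U over all removed x spared pairs, with half
   credit for ties,
   $$D_{RS} = \frac{\#\{(r,s): S_s > S_r\} + \tfrac12\#\{\text{ties}\}}{n_R\, n_S}.$$
   0 means every removed node out-ranks every spared node (the resection
   captured the hubs); 0.5 means indistinguishable; 1 the reverse.
5. **Group inference.** Outcome discrimination of D_RS (AUC with a
   logit-transformed Hanley-McNeil confidence interval and a one-tailed
   rank-sum test, directed at seizure-free patients having *lower* D_RS),
   plus duration-connectivity regressions: a robust bisquare fit of mean
   connectivity on log10 duration per segment, and a random-intercept mixed
   model pooling segments.

## The synthetic cohort generator

Because no patient recordings are distributed, the package ships a
first-class generator whose output has the statistical structure the
analysis assumes. Region $i$ of hemisphere $H(i)$ follows a factor model

$$x_i(t) = \lambda_i\, g_{H(i)}(t) + \mu\, c(t) + \sigma\, \varepsilon_i(t),$$

with independent unit-variance white Gaussian processes $g_L, g_R$ (one per
hemisphere), $c$ (global), and $\varepsilon_i$ (per-region noise). Hubs get
loading `loading_hub` (default 0.9), other regions `loading_base` (0.4), the
global factor `loading_global` (0.2) is the only inter-hemispheric coupling,
and `noise_sd` is 1. The factor structure guarantees a valid (positive
semidefinite) covariance and closed-form pairwise correlations
(`population_fc()`), e.g. within hemisphere
$\rho_{ij} = (\lambda_i\lambda_j + \mu^2) / \sqrt{(\lambda_i^2+\mu^2+\sigma^2)(\lambda_j^2+\mu^2+\sigma^2)}$ —
which is what makes sharp convergence and recovery tests possible.

Two effects are planted:

* **Outcome effect.** Each hub of the resected hemisphere falls inside the
  resection with probability `hub_hit_fraction_good` (0.9) for seizure-free
  subjects and `hub_hit_fraction_poor` (0.1) otherwise; the resection is
  filled to `resection_size` with non-hub regions of the same hemisphere.
* **Duration effect.** All loadings are scaled by
  $1 + \texttt{duration\_slope}\cdot\log_{10}(\text{duration})$
  (slope 0.05), the simplest mechanism that makes mean connectivity increase
  monotonically with log duration. Durations are log-uniform over 1-40
  years so $\log_{10}$ duration is uniform.

Default cohort shape: 31 subjects, 12 seizure-free, 114 regions (57 per
hemisphere, the scale at which the cohort-level findings were most
consistent), 600 Hz, 4 hubs per hemisphere, resections of 8 regions
(about 14% of a hemisphere, a typical temporal-lobe extent).

What the generator deliberately does **not** emulate: interictal spikes and
artifacts (the sliding-window average captures stationary correlation
structure, and spikes confined to a minority of windows have limited
influence), nonstationarity within a recording, field spread / source
leakage, and any sensor-space physics — synthetic data enter the pipeline
*after* source localization. Passing recovery tests therefore demonstrates
that the statistical machinery recovers planted effects of realistic size
under the model's assumptions, not that those assumptions hold in real MEG.

## Numerical and design choices

* **Raw-r averaging.** Window matrices are averaged without a Fisher
  z-transform, matching the plain temporal-average definition of the epoch
  network; negative correlations are kept as-is.
* **Trailing samples.** Only complete windows enter
  (`floor((T - win)/step) + 1` of them), keeping every estimate at equal
  sample size. Window length is `round(seconds * fs)`.
* **Epoch placement.** `select_epochs()` draws the requested number of
  epochs (fewer if the recording cannot hold them at the required 5-minute
  separation) uniformly over all feasible ordered placements, by sorting
  iid uniform offsets into the recording's slack. A rejection sampler was
  rejected (sic): with near-zero slack its acceptance probability vanishes,
  while the direct construction always terminates and can place epochs
  flush — a 7-minute recording at 600 Hz yields exactly two flush epochs.
* **Ties.** D_RS and the group AUC give ties half credit (midranks); this
  is required for identical strengths to score exactly 0.5, and both
  routes are property-tested against exhaustive pair enumeration.
* **Spared scope.** By default the spared side of D_RS includes non-removed
  regions of *both* hemispheres (contralateral hubs are informative
  precisely because they were not removed); strengths remain
  intra-hemispheric either way. `spared_scope = "ipsilateral"` restricts
  the comparison to the resected hemisphere.
* **Strength as mean, not sum.** For equal hemisphere sizes the two are
  rank-equivalent, so D_RS is unchanged; a unit test asserts this.
* **AUC interval.** The Hanley-McNeil standard error with
  $Q_1 = A/(2-A)$, $Q_2 = 2A^2/(1+A)$ is mapped to the logit scale and
  back, which keeps both bounds inside (0, 1); with $A=0.76$ and groups of
  12 and 19 this construction gives the interval 0.54-0.90 to two decimals,
  the package's reference worked example.
  Degenerate AUCs (0 or 1) have no logit interval and are reported as a
  point, explicitly.
* **Rank-sum test.** Exact enumeration for tie-free samples with
  $n_1+n_2 \le 12$, otherwise the normal approximation with tie and
  continuity corrections — so the 12-vs-19 cohort comparison uses the
  approximation, as standard implementations would.
* **Robust LRT.** Bisquare M-estimation has no canonical likelihood, so the
  per-segment duration model is compared with its intercept-only null via
  Gaussian quasi-likelihoods evaluated at the robust estimates (MLE scale),
  chi-square with 1 df. Simulation shows the resulting test holds its
  nominal type-I error at cohort size (about 5-6% at n = 31). The adjusted
  $R^2$ uses bisquare-weighted sums of squares.
* **Mixed model.** `mean_fc ~ 1 + log10(dur) + (1 | segment)` by maximum
  likelihood against the null without the duration term; singular fits of
  the 3-level random intercept are tolerated (variance 0 is a legitimate
  boundary estimate). A single segment is an error, pointing the caller to
  the per-segment robust fit.
* **Uncorrected per-segment p-values** are reported as such; all segments
  are emitted so users can correct downstream if they wish.
* **Determinism.** Every stochastic step takes an explicit seed. The signal
  simulator owns a dedicated `std::mt19937_64` stream and never touches R's
  RNG state; R-level sampling (epochs, resections, durations) runs inside a
  save/restore wrapper, and per-subject substreams derive from the master
  seed, so cohorts are reproducible while subjects stay independent.
  Identical configuration + seed reproduces `group_stats.json` byte for
  byte.

## Problem sizes used in the shipped tests

The validation suite runs cohorts of 31 subjects (12/19 outcome split, 114
regions) with 10-second simulated recordings per subject — nine 2-s windows
per network — for the planted-effect and null sweeps (50 and 200 seeds), and
n = 100 single-segment plus 31 x 3-segment cohorts (50 seeds each) for the
duration analyses. Ten seconds of the stationary factor model is enough for
the per-edge sampling error (about 0.013 SD per correlation) to leave the
planted hub/non-hub strength contrast clearly resolvable, which is the
regime the method operates in; convergence of the empirical network to the
analytic `population_fc()` is checked separately at 120 s.

## A worked run

```{r, eval = FALSE}
cfg <- run_config(cohort = cohort_config(record_minutes = 10 / 60, seed = 7))
res <- run_pipeline(cfg, output_dir = "hubdrs_run")
res$stats$segments$segment_1$outcome
res$stats$segments$segment_1$duration
```

## Known limitations

* The generator is stationary and Gaussian; heavy-tailed amplitude
  dynamics, spikes, and source-leakage-induced spurious correlation are out
  of scope, so real-data performance is not certified by these tests.
* The quasi-likelihood LRT for the robust fit is a pragmatic, not a
  canonical, test; its calibration is demonstrated by simulation at cohort
  scale only.
* Resection labeling assumes the parcellation and mask volumes are already
  co-registered; no registration or brain-shift handling is provided.
* The mixed model treats segment, not subject, as the random effect —
  a deliberate modeling choice of the analysis this package operationalizes — so repeated
  subjects act as pseudo-replicates in the pooled duration analysis.
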