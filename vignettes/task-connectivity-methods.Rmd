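---
title: "Task-based connectivity and graph topology: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Task-based connectivity and graph topology: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cppigraph)
```

This vignette documents the models implemented in **cppigraph**, the
assumptions behind them, the tunable parameters, and the design choices made
where a published description left the construction open. The package targets
a specific class of study: task-fMRI comparisons of functional network
architecture between groups (here, young vs. older adults performing a paced
semantic word-retrieval task against a counting control), carried through
ICA-derived networks, correlational PPI connectivity, OMST-filtered graphs,
and permutation / mixed-model inference.

## The analysis chain

1. **Network mapping** (`jaccard_index`, `assign_networks`, `build_rois`,
   `coverage_filter`): spatial ICA component maps are labeled by their
   Jaccard overlap `J = |A ∩ B| / |A ∪ B|` with template network masks
   (acceptance threshold `J ≥ 0.15`; components best matching the same
   template are merged when the union improves `J`). Labeled maps are
   parcellated into 5-mm peak spheres intersected with their suprathreshold
   clusters (≤ 3 peaks per cluster), and ROIs with zero signal coverage in
   more than 15% of participants are excluded. A second, stricter
   harmonization rule — drop any node with zero coverage in *any*
   participant — is exposed separately (`coverage_filter(strict = FALSE,
   max_missing_fraction = 0)`), since equal node counts are required before
   graph metrics are compared.

2. **Denoising** (`build_confound_matrix`, `denoise`): one joint
   least-squares projection per run onto the 24-parameter motion expansion
   (6 realignment parameters, temporal derivatives, squares of all 12),
   optional global signal, aCompCor component regressors, 18 discrete-cosine
   drift terms, and one-hot spike regressors for volumes with framewise
   displacement above 0.9 mm. Residuals are demeaned and are orthogonal to
   every retained regressor by construction.

3. **Connectivity** (`cppi_matrix`): correlational psychophysiological
   interaction. Each node's series is Wiener-deconvolved against the
   canonical double-gamma HRF, multiplied by the mean-centered psychological
   contrast vector (fluency vs. counting boxcar), and reconvolved to form a
   PPI term. For every node pair the partial correlation between PPI terms —
   controlling for both observed series, the convolved task regressor, and
   the per-volume motion series — is Fisher z-transformed; run matrices are
   averaged.

4. **Graph topology** (`zero_negative`, `system_segregation`, `omst`,
   `global_efficiency`, `participation_coefficient`, `define_hubs`):
   negative weights are zeroed for segregation/integration/hub analyses
   (signed matrices are kept for within/between-network summaries and
   edge-wise inference). Brain system segregation is
   `(Z̄_w − Z̄_b) / Z̄_w`; global efficiency is the mean inverse shortest
   path under reciprocal-weight distances; the OMST accumulates
   edge-disjoint MSTs until global cost efficiency (efficiency − cost)
   peaks; connector hubs are nodes with normalized participation coefficient
   at least 1 SD above their group's mean.

5. **Inference** (`nbs`, `qcfc`, `lrt_network_model`, `behavior_models`):
   network-based statistic with covariate adjustment and Freedman–Lane
   permutation of the maximal suprathreshold component size; QC–FC motion
   benchmarking; ML-fitted mixed models with likelihood-ratio tests, sum
   coding, and Bonferroni–Holm correction across measures.

## The synthetic cohort generator

The generator (`simulate_design`, `cohort_spec`, `simulate_subject`,
`simulate_cohort`, `simulate_behavior`, `simulate_component_maps`) exists so
that every downstream stage can be validated against known truth. It emulates:

* a two-condition block design — 43-s task blocks separated by 16-s rests,
  each block a 2-s cue plus 9 trials with uniform 2–4 s inter-trial jitter,
  TR = 2 s; ten fluency and ten counting blocks give the reference
  19.4-minute run, and 616 acquired minus 29 discarded volumes give the 587
  analyzed volumes;
* multi-subject ROI time series with a 7-community modular latent
  covariance whose within/between-community coupling switches by condition
  and differs by age group, convolved with the canonical HRF and observed
  under AR(1) noise;
* motion: random-walk realignment parameters, Power-style framewise
  displacement, and Poisson-rate spikes that jump FD above 0.9 mm and inject
  transient global signal offsets;
* trial-level behavior: Bernoulli accuracy through a logistic link and
  lognormal response times, both driven by intercept + measure + age +
  measure × age + difficulty (+ task) with subject and category random
  intercepts.

**Study conditions (generator defaults, chosen once).** During fluency,
young adults couple at 0.5 within / 0.1 between networks and older adults at
0.3 / 0.3 — i.e. the old group is the young group with within-coupling −0.2
and between-coupling +0.2, the planted age contrast. Counting (0.3 / 0.1)
and rest (0.2 / 0.0) are identical across groups, so all group differences
are task-conditional. Observation noise is AR(1) with coefficient 0.3 and
unit innovation SD; the latent signal SD is 1.5, i.e. a contrast-to-noise
ratio in the range where single-run connectivity estimates are informative
but clearly noisy, as in real task fMRI. The HRF is the SPM-convention
double gamma (peak 6 s, undershoot 16 s, ratio 6). The spike rate defaults
to 1 per run. Inter-trial jitter is uniform on [2, 4] s and absorbed within
the block budget; cue periods do not enter the task regressor by default
(`include_cue` exposes the alternative). In the simulator the HRF kernel is
normalized to unit energy so that convolution smooths in time without
shrinking the marginal signal variance.

**What the generator does not emulate.** There is no voxel-level 4-D BOLD
(generation is at node resolution; spatial maps are separate fixtures), no
physiological noise structure beyond AR(1), no susceptibility or slice-timing
artifacts, and the confound regressors are synthetic series rather than
tissue-derived components. Passing recovery tests therefore demonstrates that
the estimators are correct and directionally sensitive under the stated
generative model — not that they are robust to every artifact of real data.

## Numerical choices and open-construction decisions

* **Seeds.** One master seed; every subject, run and stage consumes a stream
  derived by a stable polynomial string hash (`derive_seed`), so data are
  bit-reproducible and independent of generation order.
* **Covariance repair.** User-specified block couplings that are not a valid
  correlation matrix are repaired by eigenvalue clipping at zero followed by
  rescaling to unit diagonal, with a warning.
* **Deconvolution.** The published construction names deconvolution but not
  an algorithm; we use frequency-domain Wiener deconvolution with Tikhonov
  regularization at `1e-2` of the peak spectral power (configurable), plus a
  pass-through option for sensitivity checks.
* **Motion in the partial correlation.** A per-subject scalar (mean FD)
  cannot be partialled out of a within-subject correlation over time, so the
  per-volume FD series enters the cPPI control set; the subject-level mean
  FD is reserved for the group models.
* **What cPPI measures.** With a bipolar contrast vector the PPI-term
  covariance weights coupling by the squared psychological vector, so cPPI
  reflects task-window-weighted coupling: a pair with constant coupling
  across the whole run retains a positive (smaller) z, and task-modulated
  pairs stand above it. The group comparisons inherit this property from the
  construction; the package's recovery tests validate the group *contrast*,
  which is what the downstream inference uses.
* **MST tie-breaks.** Kruskal on distances 1/weight with a stable sort on
  (distance, smaller node id, larger node id) — deterministic across
  platforms; `igraph::mst` serves as an independent cross-check in the
  tests, with exhaustive spanning-tree enumeration as the oracle on small
  graphs.
* **OMST scale.** Global efficiency scales with the weights while cost does
  not, so the raw trace's maximizer would depend on the measurement scale.
  The GCE trace is therefore computed on weights rescaled by the graph
  maximum, making the selected edge set invariant under positive rescaling
  and putting efficiency and cost on a common [0, 1] scale. The selected
  adjacency is returned at its original weights.
* **Normalized participation coefficient.** Implemented exactly as printed:
  `1 − sqrt(B₀ Σ_m ((k_i(m) − k_i(m)_rand) / k_i)²)` with the weighted
  degree (strength) as `k`, the median over 100 degree-preserving
  double-edge-swap nulls (weights reassigned by permutation) as
  `k_i(m)_rand`, and `B₀` a configurable constant defaulting to 1 (the
  source formulation does not define it). The hub rule uses the sample
  (n−1) standard deviation.
* **Efficiency conventions.** Unreachable pairs contribute 0 to global
  efficiency; this is required for the proportional-threshold comparison,
  where thresholded graphs may disconnect (flagged in the output).
* **NBS.** Component size is edge count (extent). Covariates are handled by
  Freedman–Lane permutation: edges are residualized on the covariate-only
  model, residuals permuted over subjects, and the full design refit.
  Thresholds may be given as a one-sided p (converted via the design's
  residual df, which is reported) or as an explicit t. Permutation p-values
  use the add-one rule and can never be exactly zero.
* **Mixed models.** All LRT comparisons are between ML fits (REML is never
  used where fixed effects are tested). Categorical predictors are
  sum-coded with old = +1; connectivity measures, FD and education are
  mean-centered before interactions are formed. RT models use the natural
  log of response time and correct fluency trials only. A network measure
  that is exactly constant within every subject is collapsed to one row per
  subject and tested with a fixed-effects model.

## Problem sizes and calibration regime

The validation suite runs at deliberately modest sizes chosen for tight
replication loops: oracle checks on 5–8-node graphs (where exhaustive
enumeration is feasible), recovery runs at 15 subjects per group on 21-node,
7-community cohorts with single 10+10-block runs, filtering comparisons on
104-node matrices (the reference graph size), and null calibrations with
200–400 replicates. Mixed-model type-I calibration is assessed at 30
subjects per group (the generative cohort size) for the trial-level
behavioral models and at 100 per group for the subject-level network-measure
LRT, where the chi-square reference distribution is accurate.

## Known limitations

* ML likelihood-ratio tests of between-subject effects are mildly
  anticonservative in small samples (≈0.08–0.11 at 15 subjects per group in
  our null simulations); this is a known property of chi-square reference
  distributions with few independent units, not specific to this
  implementation. At the generative cohort size and above, the tests are
  calibrated. Small-sample corrections (e.g. parametric bootstrap) are out
  of scope.
* The OMST on small or very sparse graphs often terminates after a single
  MST round, because one spanning tree already carries a large share of the
  total weight; multiple rounds become typical at the reference graph size.
* cPPI entries for node pairs with degenerate (constant) PPI terms are
  reported missing and excluded pairwise from averages, never imputed.
* The binomial behavioral models flag but do not correct separability risks
  (subjects at floor or ceiling accuracy).
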