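---
title: "Restriction spectrum imaging, deep learning, and patient-level csPCa detection: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Restriction spectrum imaging, deep learning, and patient-level csPCa detection: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rsipipe)
```

# The problem

Multiparametric prostate MRI is read by radiologists on the ordinal PI-RADS
scale (1–5), which carries substantial inter-reader variability. Two
quantitative complements are implemented here: a diffusion-microstructure
biomarker (the restriction score from restriction spectrum imaging, RSI) and
3D convolutional classifiers operating directly on biparametric MRI volumes.
The clinically relevant endpoint is *patient-level* detection of clinically
significant prostate cancer (csPCa, Gleason grade group ≥ 2) — i.e., should
this patient undergo biopsy — rather than lesion localization.

This package provides every stage as tested, reusable code: a synthetic
multi-center cohort generator, the RSI compartment fit and RSIrs\_max
biomarker, 3D DenseNet classifiers with scalar late fusion, logistic fusion
with PI-RADS, and a leave-one-center-out (LOCO) evaluation suite with
bootstrap, reclassification, calibration, decision-curve and heterogeneity
statistics.

# The RSI signal model

The multi-b-value diffusion-weighted signal at voxel $v$ is modeled as a
linear combination of exponential decays over four tissue compartments —
restricted intracellular water ($C_1$), hindered extracellular water
($C_2$), free water ($C_3$) and vascular flow ($C_4$):

$$ S(v, b) \;=\; S_0(v) \sum_{i=1}^{4} C_i(v)\, e^{-b D_i}, $$

with fixed compartmental diffusion coefficients $D_1 < D_2 < D_3 < D_4$.
The per-voxel coefficients are obtained by nonnegative least squares
against the design matrix $A_{ji} = e^{-b_j D_i}$:

```{r}
round(build_design_matrix(c(0, 200, 1000, 2000, 3000),
                          c(1.0e-4, 1.8e-3, 3.6e-3, 1.0e-2)), 4)
```

Because there are only four compartments, the constrained fit is solved
*exactly* by enumerating all 15 candidate support sets per voxel in one
vectorized pass and keeping the feasible solution with the smallest
residual; the convexity of the problem guarantees this recovers the global
NNLS optimum. The test suite cross-checks this against an independent
per-voxel active-set solver. Nonnegativity is the default because signal
fractions are physical quantities; an unconstrained fit is available for
diagnostics. Voxels with zero signal at every b-value fit to zeros rather
than NaN so that downstream map arithmetic stays safe.

The restriction score and the patient-level biomarker are

$$ \mathrm{RSIrs}(v) = s \cdot \frac{C_1(v)}{\operatorname{median}\{T2W(u) : u \in \text{prostate}\}},
\qquad \mathrm{RSIrs}_{\max} = \max_{v \in \text{prostate}} \mathrm{RSIrs}(v). $$

The scale factor $s$ (`rsirs_scale`, default 1) is exposed rather than
fixed: published clinical operating thresholds for RSIrs\_max imply a
site-calibrated scale convention that is not derivable from the definition,
so guessing one would create false comparability. The C1 *coefficient* (not
its fraction of total signal) enters the numerator, matching the biomarker's
definition as the C1 signal intensity normalized by the in-prostate T2W
median.

**Compartmental ADC defaults.** The values shipped as defaults
(`1.0e-4, 1.8e-3, 3.6e-3, 1.0e-2` mm²/s) are externally sourced from the
prostate RSI literature, where they were determined empirically; they are
not estimated by this package and should be overridden to match an
acquisition when known. Estimating $D_i$ from data is deliberately out of
scope — the model is linear precisely because the decay constants are fixed.

# The synthetic cohort generator

Clinical multi-center imaging data cannot be redistributed, so the
generator produces cohorts with the *statistical structure the analysis
assumes*, making every downstream stage testable:

* **Multi-site structure.** `reference_cohort_characteristics()` ships a
  seven-center summary table (cases, csPCa counts, biopsy-naïve
  biopsy-confirmed (BN-BC) counts per center; 1846 cases, 721 csPCa, 876
  BN-BC in total) and `default_site_profiles()` turns it into per-site
  prevalences and cohort-flag mixes. A `scale` argument shrinks patient
  counts for desk-scale runs.
* **PI-RADS scores.** Drawn from label-conditional distributions
  $P(\text{PI-RADS}=k \mid \text{csPCa})$ and
  $P(\text{PI-RADS}=k \mid \text{benign})$. These conditionals are not
  identifiable from published marginal tables, so the defaults were chosen
  once such that the implied marginal at 39% prevalence matches the
  reference cohort's marginal PI-RADS distribution (≈ 35/3/14/25/24% for
  scores 1–5); a χ² goodness-of-fit test in the suite confirms the draws.
* **Imaging forward model.** The prostate is a centered ellipsoid (semi-axes
  38% of the field of view); background compartment fractions are the
  configured values with a mild smooth spatial perturbation, renormalized to
  sum to one; csPCa-positive patients receive one or two spherical lesions
  (radius 3–6 mm by default) inside the mask where the restricted fraction
  is multiplied by `lesion_c1_contrast` (default 6) and renormalized. DWI
  volumes follow the four-compartment forward model above and are corrupted
  with Rician noise, $\sqrt{(S+n_1)^2+n_2^2}$, $n_i \sim N(0,\sigma)$ — the
  standard magnitude-MRI convention. T2W is an independent smooth positive
  field.
* **Determinism.** All randomness flows from the cohort seed; each patient
  additionally carries a derived private seed so volumes can be synthesized
  in any order or subset.

Default grid is 32×32×24 voxels at 1×1×3 mm — deliberately desk-scale
volumes that still exercise genuinely 3D code paths; tests mostly use even
smaller grids. The default b-value set {0, 200, 1000, 2000, 3000} s/mm²
provides at least as many measurements as compartments, which the fit
requires.

**What the generator does not emulate** — and hence what green tests do
*not* establish: realistic prostate anatomy and zonal structure, scanner
artifacts (eddy currents, B0 distortion, gradient nonlinearity), inter-site
protocol differences beyond noise level and case mix, Gleason-grade
structure beyond the binary csPCa label, and the empirical correlation
structure between PI-RADS errors and image appearance. Passing tests
demonstrate that the algorithms are implemented correctly and behave as the
theory predicts under the stated generative model, not that the clinical
performance figures transfer to real cohorts.

In this synthetic world, with zero noise and lesion contrast above one,
RSIrs\_max separates positive from negative patients perfectly (a property
the suite asserts); real data are far harder. Noise σ is therefore the main
difficulty dial, and the recovery-error tests verify the fit degrades
monotonically in it.

# The 3D DenseNet classifiers

Two variants are implemented: a 3-channel model on biparametric MRI (T2W,
ADC, high-b DWI) and a 5-channel model that adds the RSI C1 and C2
coefficient maps and late-fuses the RSIrs\_max scalar. The architecture is a
3D densely connected network: convolutional stem, four dense blocks
(pre-activation ReLU + 3×3×3 convolution per layer, outputs concatenated)
separated by transitions (1×1×1 compression convolution + 2× average
pooling), global average pooling, and a linear head. In the scalar-fusion
variant the pooled vector is reduced to `fusion_width` (default 5) features,
concatenated with the standardized RSIrs\_max, and mapped by a final linear
layer to the two class scores. The full-scale configuration reproduces the
published channel progression:

```{r}
channel_trace(densenet_config(in_channels = 5, preset = "paper"))
```

The network, backpropagation, and the AdamW optimizer are implemented
directly in vectorized R (im2col gathers plus BLAS matrix products); the
gradient path is verified against finite differences in development and the
training loop is exercised by capacity and determinism tests. The `tiny`
preset (stem 8, growth 4, blocks 2-2-2-2) is the tested, desk-scale
configuration; the `paper` preset is retained for structural fidelity but
is not required by any test.

Training choices, with rationale where the choice was open:

* **Loss.** Binary cross-entropy over a two-way output head, implemented as
  the two-class cross-entropy — mathematically identical for the binary
  case.
* **Optimizer.** AdamW (decoupled weight decay) with peak learning rate
  0.001. Weight decay defaults to 0.01, the AdamW convention; biases are
  not decayed.
* **Schedule.** Linear warm-up to the peak rate followed by cosine annealing
  to zero. The warm-up length is 10% of total optimizer steps by default —
  a conventional figure, exposed in `train_config()`.
* **Best-epoch selection.** A stratified 10% of the training fold (matched
  by csPCa status) is withheld strictly for selecting the best epoch —
  never for hyperparameter tuning. The selection metric defaults to
  validation AUC, with validation loss available.
* **Scalar standardization.** RSIrs\_max is z-scored with training-fold
  statistics before entering the fusion head (flag-controlled), since the
  raw biomarker scale is arbitrary relative to the learned features.
* **Augmentation.** Left-right flips, integer translations of at most two
  voxels, and mild multiplicative intensity jitter — conservative,
  label-preserving transforms; disabled by default in the tests.

Input tensors are cropped (or zero-padded) to a fixed shape centered on the
prostate-mask bounding box and z-scored per channel with bounding-box
statistics (standard deviation floored at 1e-6 so constant channels map to
zero). Bounding-box rather than whole-volume statistics stabilize
normalization across synthetic "sites" with different noise levels. The ADC
channel is the mono-exponential log-slope over b ≤ 1000 s/mm² (the
conventional clinical range, configurable); the high-b channel is the
acquired volume at the largest b-value — the simplest defensible choice
when it is unknown whether a high-b image was acquired or synthesized.

# The seven-model roster and logistic fusion

1. PI-RADS (univariable logistic),
2. RSIrs\_max (univariable logistic),
3. bpMRI CNN probability,
4. bpMRI+RSI CNN probability,
5. PI-RADS + RSIrs\_max,
6. PI-RADS + model-3 probability,
7. PI-RADS + model-4 probability.

Fusion models are unpenalized maximum-likelihood logistic regressions with
Wald 95% CIs. PI-RADS enters as a numeric 1–5 covariate; potential
nonlinearity in that mapping is a documented limitation shared with the
source analysis. Under perfect separation the fit falls back to a weakly
ridge-penalized IRLS solve and flags the returned specification. All
logistic models are refit within each LOCO fold on training-fold patients
only — the conservative, leak-free reading of the protocol — and
`run_model_roster()` refuses to fit if any training row belongs to the
held-out site.

# Evaluation

`loco_split()` holds out one center entirely; a stratified 10% of the
remainder forms the internal validation set; sites designated always-train
(by default the smallest site, when more than two exist) never rotate into
the test fold. Aggregating each fold's held-out predictions scores every
patient exactly once in an external-validation setting, and the evaluation
is restricted to the BN-BC subset — patients who were biopsy-naïve at MRI
and biopsy-confirmed afterwards — because only they have labels untainted
by prior-biopsy knowledge.

Statistics, with the conventions chosen where the literature admits
variants:

* **AUC**: Mann–Whitney with ties counted ½.
* **Average precision**: step-wise sum of precision × recall increments.
* **Operating point**: the largest threshold (calls at score ≥ threshold)
  whose sensitivity is ≥ 0.90. This rule reproduces a discrete PI-RADS
  cutoff without interpolation; an interpolated variant would blur the
  published "PI-RADS 4"-style thresholds. ΔSpec is the specificity
  difference versus the reference model at each model's own operating
  point.
* **NRI**: the *continuous (category-free)* variant — no risk categories
  are defined for this problem, and the choice matters when comparing NRI
  values across publications, so it is stated prominently. IDI is the
  difference in discrimination slopes.
* **Bootstrap**: percentile method (2.5th–97.5th percentiles), 10 000
  resamples at full scale (reduced in tests for runtime), every statistic —
  including the operating threshold — recomputed inside each resample.
  Paired-difference p-values are two-sided sign probabilities,
  $2\min(\Pr(\Delta \le 0), \Pr(\Delta \ge 0))$, floored at $2/B$.
  Degenerate single-class resamples are redrawn and counted. Site-level
  clustering preserves site strata (resampling patients within sites);
  resampling whole sites is available behind a flag because the phrase
  "site-level clustering" is genuinely ambiguous.
* **Point estimates**: both the full-sample statistic and the bootstrap
  median are emitted; the bootstrap median is labeled primary in the
  rendered table to match the "median (95% CI)" reporting convention.
* **Multiplicity**: Bonferroni over the seven comparisons, 0.05/7 ≈ 0.007.
* **Heterogeneity**: fixed-effect Cochran's Q with inverse-variance weights
  from within-site bootstrap SEs; $I^2 = \max(0, (Q-(k-1))/Q) \cdot 100$.
  The weighting scheme is a choice (the statistic's name alone does not fix
  it) and is stated here for reproducibility.

```{r}
bonferroni_alpha(0.05, 7)
cochran_i2(c(0.6, 0.8), c(0.05, 0.05))[c("cochran_q", "i_squared")]
```

# Problem sizes

The package's own examples and tests run at deliberately small scale: grids
of 12–16 voxels per axis, two-site cohorts of 30–60 patients, the tiny
network preset, 2–10 training epochs, and 100–1000 bootstrap resamples.
These sizes were chosen so that a full end-to-end LOCO run with two trained
CNNs per fold completes in tens of seconds while still exercising every
code path (dense connectivity, pooling, fusion, stratified splits,
bootstrap recomputation). Full-scale settings — the `paper` network preset,
10 000 bootstrap resamples, larger grids — are plain configuration changes.

# Known limitations

* The synthetic world is much easier than clinical data; absolute
  performance numbers from synthetic runs are not comparable to published
  clinical results and are not meant to be.
* The hand-implemented network trains single-threaded on CPU; it is meant
  for desk-scale scientific verification, not large-scale training.
* PI-RADS nonlinearity, reader effects, and clinical covariates (age, PSA,
  volume) are out of scope.
* No Rician-bias correction is applied before the compartment fit; the
  upstream noise-correction chain of a scanner pipeline is explicitly
  replaced by the synthetic forward model.
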