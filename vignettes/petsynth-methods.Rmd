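---
title: "Cross-tracer PET synthesis and its evaluation: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-tracer PET synthesis and its evaluation: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(petsynth)
```

## The problem

Amyloid PET establishes whether fibrillar β-amyloid (Aβ) is deposited in a
patient's brain — the gating question for anti-amyloid therapy — but the scan
is expensive and far less available than ^18^F-FDG PET, which images glucose
metabolism. `petsynth` implements and evaluates a cross-tracer translation
pipeline: a 2D conditional GAN that maps axial FDG slices to amyloid-PET-like
slices, restacked into volumes, followed by the quantitative battery a reader
would use to decide whether the synthetic images are usable — image-quality
metrics, regional voxel values, white/gray-matter contrast, and a binary
Aβ-status classifier acting as an "artificial neuroradiologist".

Because clinical paired FDG/amyloid studies cannot be redistributed, the
package ships a digital phantom generator that produces paired cohorts with
the statistical structure the analysis relies on. Every stage of the
pipeline, including the GAN, runs and is tested end to end on these phantoms.

## The translator

The translator is the pix2pix design: a U-Net generator against a
conditional PatchGAN discriminator.

* **Generator.** For `image_size` $S$ (a power of two), the encoder applies
  $\log_2 S - 1$ stride-2 $4\times4$ convolutions whose channel counts double
  from `base_channels` up to a cap of `8 * base_channels`, each followed by
  instance normalization (except the first stage) and leaky-ReLU (slope 0.2).
  The decoder mirrors this with stride-2 transposed convolutions, skip
  concatenation from the matching encoder stage, dropout 0.5 on the three
  innermost stages, and a final tanh producing one output channel.
* **Discriminator.** The 70×70 PatchGAN: the FDG slice and a (real or
  synthetic) amyloid slice are channel-concatenated and passed through three
  stride-2 and two stride-1 $4\times4$ convolution stages, yielding a 2D map
  of patch scores (14×14 for 128×128 inputs).
* **Losses.** Least-squares adversarial objectives for both networks, plus
  `lambda_l1 = 100` times the mean absolute error between generated and real
  amyloid slices for the generator. Both networks use Adam
  (`learning_rate = 2e-4`, `beta1 = 0.5`, `beta2 = 0.999`).
* **Training data.** Axial slices whose brain fraction is at least
  `brain_fraction_min` (default 0.01); minibatches are balanced to hold
  exactly half positive-case and half negative-case slices, the minority
  class oversampled with replacement until the majority class is exhausted
  each epoch.

The conv-net core is implemented in the package's own C++ (im2col/GEMM
convolutions in float32) with deterministic seeding of weight
initialization, batch shuffling and dropout, so identical configurations
reproduce identical loss histories and outputs on a fixed platform.

Design choices where the design was genuinely open:

* **Instance normalization** rather than batch normalization: it needs no
  running statistics, making inference deterministic and independent of
  batch composition; it is a standard choice in pix2pix derivatives.
* **LSGAN adversarial loss**: stabler than the cross-entropy GAN objective at
  small batch counts, and swappable behind the training interface.
* **L1 weight 100**: the canonical pix2pix reconstruction weight.
* **Intensity scaling**: slices are mapped affinely from `[0, p99.5]` of the
  pooled training intensities to `[-1, 1]` (SUVR-like values are unbounded
  above, so a stored window keeps the map invertible and reproducible); the
  window is saved with the model and reused at inference.
* **Dropout at inference is off.** Some pix2pix implementations keep it on;
  determinism of synthesized volumes was judged more valuable here.

## The phantom cohort

The generator emulates the features of paired, co-registered,
anatomically standardized FDG/amyloid brain PET that the downstream
statistics need — no more:

* **Geometry.** A nested-ellipsoid brain on a 128×128×60 grid (1.5 mm
  isotropic): white-matter core inside a gray-matter ribbon, in-plane radii
  following an ellipsoidal axial profile so ~50 of 60 slices contain brain.
  The lowest brain slices form a cerebellar reference region; the rest is
  partitioned into left/right × five groups (frontal/insular, temporal,
  parietal, posterior cingulate/precuneus, striatum) by position along the
  anteroposterior and axial axes, applied to gray and white matter alike.
  The ten (group, hemisphere) gray-matter regions are the Centiloid-style
  feature set; each has a paired white-matter region for the contrast
  statistic.
* **FDG.** Gray matter mean 3.0, white matter 1.0, reference 2.0 (unitless
  uptake). In Aβ-positives, posterior cingulate/precuneus and parietal gray
  matter are multiplied by `hypometabolism_factor = 0.8` — the classic AD
  hypometabolism pattern. This coupling is a modelling choice: a conditional
  GAN can only recover Aβ status from information present in its FDG input,
  so the phantom must put the signal there; 0.8 is large enough to be
  learnable but not trivially thresholdable.
* **Amyloid.** White matter mean 2.0 in everyone (nondisplaceable binding);
  gray matter 1.0 in negatives and 2.0 in positives; reference 1.0.
* **Variability and physics.** Per-region ±5% uniform jitter (decorrelates
  ROI means so the regressions have scatter), a per-subject log-normal
  global scale (sd 0.1), Gaussian PSF blur of FWHM 6 mm (σ = FWHM/2.3548
  per axis, in voxels), additive Gaussian noise (sd 0.1) after the blur, a
  floor at zero, and SUVR-style normalization: FDG by the whole-brain mean,
  amyloid by the reference-region mean.

Noise is additive Gaussian after the blur — an approximation to
reconstructed PET noise, not a projection-domain Poisson model; the
evaluation statistics only need realistic variance. The phantom has no
cortical folding, no tracer kinetics and no scanner-specific resolution
model, so passing tests demonstrate that the pipeline's statistics and
learning machinery behave as designed, not that clinical accuracy would
reach any particular level on real patients.

A scaled profile (`phantom_params_small()`, 64×64×32 voxels at 3 mm — the
same physical extent, ~27 brain slices) exists so the full experiment runs
in minutes on one CPU; `gan_config_small()` (64×64, 30 epochs, batch 16,
8 base channels) is its translator counterpart. The channel width was set
once for CPU practicality at this slice size. These are the problem sizes
used by the package's tests and by `scripts/acceptance.R`.

## The evaluation battery

* **Image quality.** MSE, PSNR (`10 log10(peak²/mse)` with the real image's
  masked maximum as peak) and SSIM over the brain mask. SSIM is computed
  slice-wise in 2D — the pipeline itself is 2D — with an 11-tap Gaussian
  window (σ 1.5, replicate padding), stability constants `(0.01 L)²` and
  `(0.03 L)²` with `L` the real image's masked dynamic range, population
  covariances, and a 5-pixel border exclusion, matching the standard
  reference implementation to ~1e-6.
* **ROI voxel values.** The ten gray-matter ROI means per volume, in a fixed
  documented order (`roi_feature_order()`); synthetic-on-real OLS pooled
  over subjects, with t-based p-values and 95% CIs. ROI means (not raw
  voxels) are the regression observations — the feature definition used by
  the classifier — which resolves an ambiguity in how "voxel values" can be
  pooled.
* **White/gray contrast.** `(μW − μG)/(σW + σG)` per (group, hemisphere),
  with population (1/n) standard deviations; the sample/population choice is
  immaterial at ROI voxel counts but is fixed and tested. High in negatives,
  near zero in positives. Degenerate regions (both constant) raise an error
  rather than returning an infinity.
* **Group comparison.** One-sided Wilcoxon rank-sum (negatives greater),
  exact by enumeration when `m + n ≤ 12` without ties, normal approximation
  with tie and continuity corrections otherwise. The per-subject unit for
  this test is the mean contrast over the ten regions, keeping observations
  independent.
* **Classifier.** Gaussian-kernel logistic regression on the ten ROI means:
  penalized log-likelihood with ridge penalty `(λ/2) αᵀKα`, Newton
  iterations from zero initialization (gradient max-norm `1e-8` or 100
  iterations), median-heuristic bandwidth and `reg_lambda = 1e-3` by default
  (the hyperparameters are exposed and logged; no principled values are
  dictated by the problem). Decision threshold fixed at 0.5; stratified
  k-fold cross-validation; ROC by threshold sweep with trapezoidal AUC
  (equal to the Mann–Whitney pair-counting probability).

## The experiment design

`plan_splits()` reserves an even, class-balanced classifier set (30 of 110
cases in the full design), then partitions the remainder into class-balanced
validation folds of even size, as equal as possible — for 80 cases and 6
folds: validation sizes {12, 14, 14, 14, 14, 12}, hence training sets of 66
or 68 cases, always even. Mixed odd validation sizes (13/14) would break the
even-training-set property, which is why the even-size rule is part of the
design. The classifier cases are chosen by seeded random balanced selection
(the selection mechanism is otherwise unconstrained by the design).

`run_experiment()` fits the classifier once on the real amyloid features of
the classifier cases (recording its stratified CV accuracy first), then per
fold trains an independent translator (seeded `seed + fold`), synthesizes
the validation FDG volumes, evaluates the four domains, and classifies real
and synthetic validation volumes with the same classifier. Leakage guards
assert that the classifier cases never intersect translator cases and that
train/validation sets are disjoint. An `"oracle"` translator mode passes
the real amyloid volumes through unchanged, which pins down the plumbing:
synthetic metrics must then equal real ones exactly.

## Numerical and degenerate-input conventions

* Volumes are used in stored voxel space; no reorientation or registration
  (phantoms and synthetic outputs share one frame). Grid conformance is
  trilinear and edge-clamped over a fixed physical extent.
* Intensities are written to NIfTI as 32-bit floats.
* Normalization requires a nonempty reference region with positive mean;
  the whole-brain "region" is a pseudo-entry resolved as all nonzero labels
  (the phantom whole-brain mask therefore includes the cerebellar
  reference).
* A perfectly constant regression input, an empty ROI, a single-class label
  vector, or a zero-denominator contrast each raise an informative error
  rather than propagating NaN or infinity.
* Per-subject phantom seeds are derived deterministically from the master
  seed; all RNG flows through explicit seeds, so identical configurations
  reproduce identical cohorts, splits, loss histories and report tables.

## Problem sizes used by tests

The formula-level checks run on small hand-painted atlases and enumerated
fixtures. The statistical-structure checks simulate 20 + 20 subjects (the
full-size grid for the feature-separability and contrast-ordering checks;
the scaled grid for properties that only need the signal's presence). The
end-to-end synthesis check runs the scaled profile — 40 cases, 12 classifier
cases, 4 folds, 64×64 slices, 30 epochs, batch 16 — over three fixed seeds
and requires the four-domain criteria (pooled classifier accuracy ≥ 0.80,
positive and significant contrast regression, significant negative-positive
contrast separation on synthetic images) in at least two of the three.

## Known limitations

* The phantom's Aβ-status signal in FDG is a single multiplicative factor in
  two region groups; real FDG/amyloid coupling is far weaker and more
  heterogeneous, so phantom classifier accuracies are optimistic by
  construction.
* The translator is strictly 2D; continuity along the body axis is emergent,
  not enforced, and multi-slice conditioning is out of scope.
* The scaled profile's capacity (8 base channels) is sized to the phantom's
  complexity; clinical-resolution synthesis would use the full 128/64
  profile and correspondingly longer training.
* Checkpoints serialize with R's native format and are a runtime artifact;
  cross-language portability was not a goal.
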