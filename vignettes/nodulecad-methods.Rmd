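---
title: "nodulecad: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{nodulecad: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nodulecad)
```

## What this package does

`nodulecad` is a classical (pre-deep-learning) computer-aided detection and
diagnosis pipeline for pulmonary nodules in 2D CT slices:

1. **Denoise** the slice (mean-shift mode filtering, or explicit diffusion:
   linear, Perona–Malik, or Catte).
2. **Segment** bright foreground by adaptive (Otsu) thresholding, cavity
   filling and rolling-ball closing.
3. **Extract candidates** as 8-connected components and **prune** obvious
   non-nodules with interpretable shape/intensity rules (mean, variance,
   circularity, flatness, elongation, rectangularity).
4. **Featurize** every surviving candidate with a 17-dimensional hybrid
   vector: gray statistics (mean, variance, histogram energy
   $E_x=\sum_k H(k)^2$, entropy $H_x=-\sum_k H(k)\log_2 H(k)$,
   calcification fraction), 2D shape descriptors, GLCM texture (contrast
   $\sum_{ij}(i-j)^2 S(i,j)$ and homogeneity $\sum_{ij} S(i,j)/(1+(i-j)^2)$
   at offsets $d \in \{1,2\}$, four angles averaged), and Sobel-gradient
   statistics.
5. Optionally **reduce** features with Fisher LDA (generalized eigenproblem
   $S_b w = \lambda S_w w$).
6. **Classify** with a bank of models sharing one contract: an RBF-kernel
   soft-margin SVM trained by SMO, a **rule + SVM hybrid** (rules veto
   first, the SVM scores survivors), logistic regression trained by
   **particle swarm optimization** of the binomial log-likelihood
   $J(\theta)=\sum_i [y_i z_i - \ln(1+e^{z_i})]$, a random forest with
   majority vote and OOB error, and naive-Bayes/KNN/CART baselines.
7. **Evaluate** with confusion metrics, ROC/AUC (trapezoid = Mann–Whitney),
   split ladders, stratified k-fold CV, and a paired LDA ablation.

Everything runs on synthetic phantom slices, so the whole pipeline is
testable with no external imaging data.

## The phantom world

`phantom_spec()` states the world once; these defaults are used by every
benchmark in the test suite:

* 128×128 slices, background level 0.2, object level 0.8, additive Gaussian
  noise with sd 0.05.
* **Nodules**: hard disks (radius 5–11 px) with a ~1-pixel Gaussian edge
  feather (σ = 0.5) mimicking partial-volume blur. Malignant-like nodules
  perturb the radius with $r(\theta)=r_0\,(1+a\sum_h \sin(k_h\theta+\phi_h))$,
  $a\in[0.1,0.3]$, $k\in\{5..9\}$ — spiculated margins with lower
  circularity, the morphology reported for malignant lesions.
* **Vessels**: rotated bars (length 18–36, width 2–3.2 px; elongation ≥ 3 by
  construction) with sinusoidal along-axis intensity modulation (caliber /
  partial-volume texture). Optionally, **vessel cross-sections**: small
  bright disks, the classic compact false positive that overlaps small
  benign nodules in shape.
* **Parenchyma texture**: a rough speckle field (sd 0.08, correlation ~0.5 px)
  applied to the background only — solid nodules replace parenchyma, so
  nodule cores stay homogeneous. Without this term the phantom has no
  "textured distractor" structure at all, and texture-feature comparisons
  would be physically meaningless.
* Objects are placed with a 5 px clearance so that distinct objects remain
  distinct connected components after feathering and a radius-2 closing;
  merged blobs would otherwise be a raster artifact, not pipeline behavior.

What a green test does **not** establish: anatomical realism (no lung
boundary, ribs, Hounsfield calibration, or 3D acquisition), the difficulty
of clinical data (phantom classes are nearly separable by design), or any
of the source study's clinical performance numbers.

## Numerical and design choices

* **Mean shift** (denoising): each pixel's estimate is iterated as the
  spatial×range Gaussian-weighted mean of the *original* neighborhood
  samples — a local mode seek of the joint kernel density. Stop at max
  change < 1e-4 or 20 iterations. Spatial window radius 2·hs.
* **Diffusion**: conservative explicit 4-neighbour scheme, reflective
  boundaries (mean-preserving for the linear variant), stability bound
  0 < dt ≤ 0.25 enforced. Conductance $g(d)=1/(1+(d/\kappa)^2)$; the Catte
  variant evaluates $d$ on a Gaussian-presmoothed copy (σ = 0.8).
* **Denoising benchmark** (`noisy_step_phantom`): Gaussian noise sd 0.15
  plus 2% salt-and-pepper impulses. The impulsive component models detector
  artifacts and is what separates the diffusion family: a raw-gradient
  conductance treats an impulse as an edge and preserves it, while the
  presmoothed (Catte) conductance does not. With purely Gaussian noise on a
  clean step, Perona–Malik wins the PSNR comparison instead — the often
  quoted Catte ≥ PM ordering is a statement about contaminated noise.
* **PSNR** uses MAX = 1 on the normalized scale; identical images report
  `Inf`. **FOM** is Pratt's figure of merit with α = 1/9 and Sobel/Otsu edge
  maps. **SSIM** uses the standard constants (0.01, 0.03)² and a 7×7 uniform
  window.
* **Perimeter / circularity**: Moore boundary tracing with √2 diagonal
  weights; reduces the raster bias that pushes digital-disk circularity
  above 1 (a perfect digital disk measures ≈ 0.92–1.08). Degenerate
  (≤ 2 px) regions fall back to the circle-equivalent perimeter.
* **Axis ratios** come from second central image moments with the +1/12
  pixel-extent correction, so 1-px-wide lines have finite elongation.
* **Rule thresholds** (defaults; all overridable): mean intensity ≥
  background + 2σ, circularity ≥ 0.4, elongation ≤ 3, rectangularity ≥ 0.3,
  minimum area 10 px. Chosen a priori from the phantom geometry (nodule
  elongation < 2, vessel elongation ≥ 3); thresholds are data, not code.
* **LDA**: solved via the symmetrized whitened eigenproblem. Shrinkage
  target is the *scaled identity* $(1-s)S_w + s\,(\mathrm{tr}\,S_w/p)I$
  rather than $\mathrm{diag}(S_w)$: a feature that is constant in the sample
  (e.g. calcification ≡ 0 on clean phantoms) has zero within-class variance,
  and shrinking toward the diagonal cannot repair it. Columns are unit-norm
  with a positive-first-element sign convention, making fits deterministic
  and duplication-invariant.
* **SVM**: simplified SMO on the precomputed RBF Gram matrix, tolerance
  1e-3, default C = 1, γ = 1/(p·var) ("scale" heuristic); 5-fold grid search
  available (`fit_svm_cv`). Features are z-scored inside `fit` (scaler
  stored), matching the scale sensitivity of RBF and KNN and preventing
  leakage (the scaler is learned on training data only).
* **PSO**: 30 particles, c1 = c2 = 2, inertia decaying linearly from 0.9 to
  0.4, synchronous position updates, velocity clamp ±1 per standardized
  dimension, one particle seeded at the zero vector so the final fitness is
  never below the null model's $-n\ln 2$. Inertia endpoints are returned
  exactly (no roundoff) at iter 0 and itermax.
* **Random forest**: bootstrap size n, Gini splits over `mtry = ⌊√p⌋`
  features, vote ties broken toward the lowest class index, OOB error stored
  as the generalization-error estimate.
* **ROC/AUC**: threshold sweep over unique scores; trapezoidal area equals
  the Mann–Whitney concordance with ties counted half (verified against an
  O(n²) pair-counting oracle).
* **Coordinates** are 1-based (row, col) per R convention; bounding boxes
  are half-open.
* **I/O**: PNG (8-bit, via the `png` package) and plain ASCII PGM (16-bit)
  for images; CSV for tables; JSON for models, projections, reports and
  manifests; YAML or JSON for pipeline configs. DICOM is not supported —
  no DICOM reader exists in the supported dependency set.

## The three-class experiment

`three_class_dataset()` pairs benign slices (smooth nodules, radii 4–8) with
malignant slices (spiculated, radii 7–11), both containing vessels and
vessel cross-sections. The resulting candidate population reproduces the
qualitative separability structure reported for real nodule data: malignant
candidates are linearly separable from both other classes in shape features,
while compact non-nodules blend into the benign population (pairwise linear
classifier accuracy for benign vs non-nodule is clearly lower than for the
malignant pairs).

## Reproducibility

Every stochastic operation takes a seed and restores the caller's RNG
state. `run_pipeline()` derives per-stage seeds from the global seed
(seed + stage index); a rerun with the same config and seed is byte-identical
across every artifact (asserted in the acceptance suite).

## Known limitations

* The SMO solver is adequate for the hundreds-of-samples regime of the
  phantom benchmarks, not for large clinical feature sets.
* The mean-shift filter is a fixed-window local mode seek, not a full
  joint-domain mean-shift segmentation.
* `shape3d_features()` supports voxel stacks, but the default pipeline and
  the 17-feature roster are 2D; the 3D block is exercised only by its unit
  tests.
* No probability calibration; scores are ranking scores.
* The phantom benchmark is nearly separable at the stated noise level, so
  several classifier-ordering checks hold with ties at accuracy 1.0 — they
  confirm "no worse", not "strictly better".
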