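---
title: "Appearance-constrained GrowCut segmentation: models, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Appearance-constrained GrowCut segmentation: models, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gcgmm)
```

This vignette is the package's own account of the science it implements:
the segmentation model and its assumptions, the parameters that matter,
what the synthetic phantoms do and do not emulate, and the numerical and
design choices made where the method description left room.

## The segmentation model

A DCE acquisition gives four aligned volumes: pre-contrast $I_0$ and
post-contrast $I_1, I_2, I_3$. Malignant lesions enhance early and often
wash out; normal parenchyma enhances more slowly and diffusely
(background parenchymal enhancement, BPE). The method works on **eight
feature images** chosen to separate these temporal signatures: the four
raw volumes, three squared difference images
$\varepsilon_t(x) = (I_t(x) - I_0(x))^2$, and a tensor-trace image. For
the trace, each voxel's four intensities are packed into a symmetric
$4\times4$ matrix $A$ with $A_{tt} = i_t^2$ and
$A_{ab} = (i_a - i_b)^2$, and the sum of the three largest eigenvalues of
$A$ is taken. Two remarks on this construction:

* $A$ is assembled from squared intensities and squared differences, not
  centred covariances, although one might expect a covariance here. The
  printed rule is implemented literally; its value is that of a rotation-
  invariant summary of uptake magnitude and temporal variation.
* the entries of $A$ are non-negative but its eigenvalues need not be;
  "the three largest" is applied literally (descending by signed value).
  The output is still non-negative, since the discarded smallest
  eigenvalue is at most $\operatorname{tr}(A)/4$.

**GrowCut** then segments each feature image independently. It is a
cellular automaton over the 3D grid: every voxel carries a label
(unlabeled / tumour / background) and a strength $\theta \in [0,1]$; user
seeds start at $\theta = 1$. At each synchronous sweep a neighbour $q$
captures $p$ iff $g(|C_p - C_q|)\,\theta_q > \theta_p$ with
$g(d) = 1 - d/\max C$. Capture strictly increases $\theta_p$, so
strengths are monotone and the automaton reaches a fixpoint. The original
description fixes neither the neighbourhood nor the update schedule; this
implementation uses 26-connectivity, Jacobi (synchronous) updates, and
keeps the incumbent label on ties, which removes all order dependence.
The image is normalized to $[0,1]$ first so $g$ is scale-free. The
default iteration cap is the sum of the grid dimensions - enough for a
label to cross the volume - and hitting it raises a warning flag rather
than an error. The C++ core skips voxels whose 26-neighbourhood did not
change in the previous sweep; this is an exact optimization of the
synchronous dynamics, and the test suite asserts bit-identical labels
against a literal triple-loop R automaton.

**The appearance model** is a pair of full-covariance Gaussian mixtures
over the 8-feature vectors, one fitted to the tumour seeds and one to the
background seeds. Each mixture's size is selected by AIC over
$n \in \{2, 3, 4\}$, independently for tumour and background. Every voxel
then receives a normalized tumour similarity
$k(x,T) = p_T(x) / (p_T(x) + p_B(x))$ (computed in log space, so
underflow can only occur when both densities vanish; such voxels are
counted and labeled background), and the GMM label image is
$G(x) = 1$ iff $k(x,T) > k(x,B)$ **and** $k(x,T) > \tau$ with
$\tau = 0.75$. Reading the "similarity distances" as normalized mixture
densities is the only interpretation under which a threshold of 0.75 on
$k(x,T)$ is meaningful, since it makes $k(x,T) + k(x,B) = 1$.

**Fusion.** The final confidence map is
$$L(x) = \frac{1}{N}\sum_{i=1}^{N} S_i(x)\,(1-\gamma) + G(x)\,\gamma,
\qquad \text{mask} = \{x: L(x) > \omega\},$$
with $N = 8$ GrowCut masks and $\omega = 0.6$ by default. The weight
$\gamma$ is the $F_{\beta=0.5}$ measure - precision weighted over recall,
reflecting the heavy class imbalance between tumour and normal voxels -
computed per tumour. The method description never states *what* the
F-measure is evaluated between; this package scores the GMM volume $G$
against the GrowCut consensus ($\bar S \ge 0.5$), the only pair of label
images available per case without ground truth. It is the package's most
consequential interpretation and is therefore exposed: `gamma` can be
overridden, and the limits are exact - $\gamma = 1$ reproduces the GMM
labeling, $\gamma = 0$ mean-GC thresholding (both asserted in tests).
After thresholding, only components 26-connected to the foreground seeds
are kept. `predict(fit, omega = ...)` re-thresholds the stored map,
standing in for the interactive confidence slider.

## From user input to seeds

Three input styles are supported on a single axial slice: a careful
closed contour, a loose polygonal/rectangular ROI, and explicit
tumour/background strokes (passed through unchanged). For the first two,
the enclosed region is eroded once (so foreground stays inside the
tumour), and with $r$ = round(half the area-equivalent diameter,
$2\sqrt{\text{area}/\pi}$):

* contour: foreground = the morphological (Lantuéjoul) skeleton of the
  eroded region accumulated over $r-1$ erosion levels
  ($\bigcup_k \mathrm{erode}^k \setminus
  \mathrm{open}(\mathrm{erode}^k)$). An earlier draft used iterative
  thinning capped at $r-1$ passes; on near-convex regions thinning
  collapses to a single voxel (the medial axis of a disc is a point),
  which cannot train a mixture model, so the classical morphological
  skeleton - arguably the more literal reading of "morphological
  skeleton using $r-1$ iterations" - is used instead.
* ROI: foreground = two perpendicular lines through the eroded region's
  centroid, each extending to the region's minor-axis length (the
  equivalent-ellipse value, $4\sqrt{\lambda_{\min}}$ of the coordinate
  covariance), clipped to the eroded region.
* both: background = $\mathrm{dilate}(R, d_1) \setminus
  \mathrm{dilate}(R, d_2)$ of the *original* region with $d_1 = r$,
  $d_2 = \max(2, r-2)$.

All morphology is 2D on the input slice with the 4-connected unit disc as
structuring element (the smallest standard choice, which makes iteration
counts meaningful: $n$ dilations equal a city-block distance threshold at
$n$ - the property the test oracle uses). GrowCut propagates the
single-slice seeds into 3D. Seed extraction is fully deterministic.

Mixture fitting needs more samples than components; candidates violating
that are dropped (with a warning) rather than failing the whole fit, and
only an entirely empty candidate set is an error. This matters because a
skeleton or stroke contributes tens of voxels, not hundreds.

## Tunable parameters

| parameter | default | units | role |
|---|---|---|---|
| `omega` | 0.6 | confidence | final threshold on $L$; raising it strictly shrinks the mask |
| `tau` | 0.75 | probability | tumour-similarity gate for the GMM label image |
| `beta` | 0.5 | - | F-measure weight for $\gamma$; $<1$ favours precision |
| `gamma` | per-case | - | GMM weight in the fusion; computed as $F_{0.5}$ unless overridden |
| `n_components` | 2-4 | - | AIC candidate mixture sizes |
| `restarts` | 5 | - | EM restarts per candidate (k-means++ seeding, best likelihood kept) |
| `tol` | 1e-3 | log-lik / sample | EM stopping rule (see below) |
| `max_iters` | sum of grid dims | sweeps | GrowCut iteration cap |

FCM baseline: $c = 2$ clusters, fuzziness $m = 2$, relative tolerance
$10^{-5}$, 200 iterations, deterministic initial centres (the ROI voxels
with extreme first-post-contrast feature values); the tumour cluster is
the one whose centre has the higher post1 intensity, at membership
$> 0.5$. Its ROI is the in-plane bounding box of the background strokes,
extended across all slices to produce a volumetric mask.

## Numerical choices

* **Covariance regularization.** Each M-step covariance gets a ridge of
  $10^{-6}\,\mathrm{tr}(\Sigma)/d$ on the diagonal plus a $10^{-10}$
  absolute floor, escalated $\times 100$ (up to six times) if the
  Cholesky factorization still fails. The absolute floor is what keeps
  the noise-free phantom computable: seeds drawn from an exactly uniform
  lesion have zero trace, and a purely trace-scaled ridge would vanish
  with them.
* **EM stopping.** EM stops when the log-likelihood change per sample
  falls below `tol = 1e-3`, the convention of standard mixture libraries.
  This is a deliberate statistical choice, not merely a speed one: the
  raw likelihood of a full-covariance mixture is unbounded (components
  can collapse onto near-duplicate points), so "EM run to full
  convergence" is not a well-defined estimator, and chasing the objective
  much further systematically inflates the extra log-likelihood of
  over-sized candidates until AIC - which is not a consistent order
  selector - prefers them. With the per-sample rule, AIC recovers the
  true size of a well-separated 3-component mixture in $\ge 90\%$ of
  replicates; with a much tighter rule no correct EM implementation does.
* **AIC.** $\mathrm{AIC} = 2k - 2\log L$ with
  $k = (n-1) + nd + nd(d+1)/2$ free parameters.
* **Surfaces and distances.** A surface voxel is a mask voxel with at
  least one face-adjacent background voxel (the volume border counts as
  background); distances are Euclidean between voxel centres in mm, so
  anisotropic spacing is respected. mSD and HD95 are *directed*
  (algorithm surface to reference surface), exactly as defined; a
  symmetric variant sits behind `symmetric = TRUE` for practical use.
  HD95 uses R's default (type-7) quantile.
* **Dice.** The printed denominator "$A\cap G + A\cup G$" equals
  $|A| + |G|$ by inclusion-exclusion; the standard simplification is
  used.
* **ICC.** Fixed to ICC(2,1) - two-way random effects, absolute
  agreement, single measurement - computed from mean squares (and checked
  against an `aov` decomposition in the tests). Degenerate tables (no
  variance anywhere) return 0 with a flag.
* **GLCM.** 3D co-occurrence over the 13 symmetric unit offsets pooled
  into one matrix, both directions counted, normalized to sum 1.
  Rescaling to 0-255 happens over the *whole volume* before 24-bin
  quantization (so a global intensity shift cancels, and a mask-local
  rescale would not); entropy uses $\log_2$; homogeneity is
  $\sum p/(1+(i-j)^2)$; kurtosis is the excess convention
  (normal $\to 0$). Zero-variance matrices get correlation 0 with a
  flag.
* **Ties in feature ranking** break alphabetically; all stochastic
  stages (EM init, SMOTE, forests, bootstrap) take explicit seeds and
  restore the caller's RNG state.

## The phantom generator

`phantom_spec()` / `simulate_case()` emulate the study conditions the
pipeline is meant for: a $32\times32\times16$ voxel grid at 1 mm
spacing, an enhancing lesion - an ellipsoid with mild boundary
lobulation (default semi-axes 6, 6, 5 mm), or a "non-mass" union of
6-12 overlapping 2.5-4 mm spheres along a random arc - on a parenchymal
background that is iso-intense pre-contrast (the default uptake curve is
100 pre, 300/280/260 post, a wash-out pattern) and gains
$\text{amp}\cdot f(x)\cdot w_t$ post-contrast, where $f$ is a smooth
random field, $w = (0.6, 0.8, 1.0)$, and amp is 0.15 for mild and 0.45
for marked BPE. Additive Gaussian noise (default SD 5, i.e. 5% of
baseline) is used rather than Rician - adequate at these SNRs for
desk-scale validation. An optional smooth within-lesion texture
(`heterogeneity`) scales the lesion signal multiplicatively.

The boundary lobulation (default amplitude 0.15, zero-mean angular
modulation) exists for realism: real masses are lobulated, and a
perfectly round phantom has a degenerate single-point skeleton that would
starve the tumour mixture of training samples. The modulation preserves
volume to within a few percent. Cases whose largest cross-section is too
small to admit the seed-extraction rules are redrawn from deterministic
sub-seeds, so every generated case is usable by construction.

Three rater-style inputs are derived from the truth mask on its
largest-area slice: the exact boundary region (careful contour), the
slice-wise convex hull dilated by 3 voxels (loose ROI), and an interior
centroid cross plus an exterior ring (strokes). `simulate_cohort()` adds
synthetic subtype labels under largest-remainder rounding of the class
proportions; the subtype controls within-lesion heterogeneity
(0.05-0.30) and the wash-out tail, so classes are separable by
construction.

What the phantoms do **not** emulate: pharmacokinetic (Tofts) enhancement
kinetics, partial-volume boundaries, bias fields, motion between
timepoints, Rician noise floors, or lesions whose intensities genuinely
overlap the parenchyma. Passing tests on phantoms therefore demonstrate
correctness of the machinery and the *directional* behaviour of the
methods (e.g. the fuzzy c-means baseline segments these high-contrast
phantoms essentially perfectly, which real data would not allow), not
clinical performance.

## Study driver and problem sizes

`run_study()` runs every case $\times$ input trial through GCGMM (whose
GrowCut consensus doubles as the standalone GC method) and FCM, scores
each mask against truth, extracts the 36-feature vector per segmentation
plus one for the truth mask, and aggregates precision errors
(%CV\(_\mathrm{RMS}\), SD\(_\mathrm{RMS}\)), pairwise inter-trial Dice,
per-feature ICC, and - for two-class cohorts with at least three cases
per class - the SMOTE + random-forest LOOCV stage (SMOTE strictly inside
each training fold; 100 trees; AUC with a 2000-rep stratified bootstrap
CI). Per-case failures are logged and skipped; more than 10% failures is
an error. The test suite exercises the driver at the study-design scale
(75 cases, 3 methods × 3 trials + truth = 27,000 texture values) and a
20-case reproducibility cohort; the acceptance script uses a 20-case
cohort and a 14-case classification cohort. These sizes were chosen so a
full desk-scale replication of the machinery stays in the minutes range
on a single CPU.

One caveat worth stating for users of the classification stage:
leave-one-out AUCs on small cohorts are volatile under label permutation
(holding out a case tilts the training fold against its class - the
well-known LOOCV anti-learning artifact), so the permutation null is
reported as a mean over permutations rather than a single draw.

## Known limitations

* The $\gamma$ reference (GMM vs GrowCut consensus) is an interpretation;
  other references (e.g. against a single designated feature's mask)
  would change per-case weights.
* AIC order selection remains liberal by construction; on real, less
  Gaussian data the selected $n$ will vary across inputs.
* Seeds live on one slice; lesions with strongly disconnected
  cross-sections may propagate poorly from a single-slice input.
* The FCM baseline's ROI extension across slices is a volumetric reading
  of an in-plane definition.
* NIfTI is the only supported volume format; DICOM ingestion is out of
  scope.
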