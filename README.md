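# gcgmm

Appearance-constrained semi-automatic tumour segmentation for dynamic
contrast-enhanced (DCE) MRI, with the full evaluation and radiomics
machinery around it.

## The problem

Interactive segmentation methods such as GrowCut adapt to whatever the
user draws, which makes them accurate but *irreproducible*: three raters
giving three slightly different inputs get three noticeably different
tumour volumes, and every texture feature computed downstream inherits
that variability. Fully automatic clustering (fuzzy c-means) is stable but
often mismatches the radiologist's notion of the tumour boundary. This
package implements GCGMM, which constrains GrowCut with a tumour-specific
appearance model so that a single rough user input - a traced contour, a
loose enclosing ROI, or a pair of strokes - yields a segmentation that is
both accurate and stable across input styles. It is aimed at researchers
building radiomics pipelines on DCE-MRI who need volumetric tumour masks
at scale without consensus manual delineation.

## The method

From one pre-contrast and three post-contrast volumes, eight feature
images are built: the four raw timepoints, three squared temporal
difference images ε_t(x) = (I_t(x) − I_0(x))², and the trace of a
voxel-wise 4×4 temporal tensor (diagonal i_t², off-diagonal (i_a − i_b)²;
the trace sums its three largest eigenvalues). The user's input is
converted automatically into foreground strokes (the morphological
skeleton of the eroded region, or centroid cross-lines for an ROI) and a
background ring (dilate(region, d₁) \ dilate(region, d₂) with d₁ = r,
d₂ = max(2, r − 2), where r is half the area-equivalent contour
diameter). GrowCut — a competitive cellular automaton in which a
neighbour q captures voxel p iff g(|C_p − C_q|)·θ_q > θ_p with
g(d) = 1 − d/maxC — runs once per feature image, giving masks S_1..S_8.
Separately, full-covariance Gaussian mixtures (EM, AIC-selected size
n ∈ {2, 3, 4}) are fitted to the 8-feature vectors at the tumour and
background seeds, and every voxel is labeled tumour (G(x) = 1) when the
normalized tumour similarity k(x,T) = p_T/(p_T + p_B) exceeds both k(x,B)
and τ = 0.75. The two are fused into a per-voxel confidence

    L(x) = (1/N) Σ_i S_i(x) · (1 − γ)  +  G(x) · γ,      mask = L > ω,

with ω = 0.6 by default and γ the F_{β=0.5} measure (precision-weighted)
of G against the GrowCut consensus — so the GMM term earns its weight
per tumour. Thresholding L at other ω values reproduces the interactive
confidence slider of the original workflow (`predict(fit, omega = ...)`).

The surrounding study machinery implements segmentation scoring (Dice,
directed mean surface distance and 95th-percentile Hausdorff distance in
mm, volume-difference ratio), precision errors across repeated inputs
(%CV_RMS, SD_RMS), feature reliability (ICC(2,1)), 36 radiomics features
(4 first-order + 5 Haralick GLCM measures × 4 sequences, 24 bins on a
0-255 rescale), and a SMOTE-balanced random-forest classifier with
leave-one-out cross-validation and Gini feature ranking. A synthetic
phantom generator (enhancing lobulated masses or non-mass blob clusters
on a parenchymal background with mild/marked background enhancement)
makes the whole pipeline testable without patient data.

## Worked example

```r
library(gcgmm)

case <- simulate_case(phantom_spec(noise_sd = 5, heterogeneity = 0.1,
                                   rng_seed = 7))
case
#> Synthetic DCE case (mass, mild BPE): lesion 789 voxels (789 mm^3)

fit <- gcgmm(case$series, case$inputs$roi)   # loose-ROI input variant
summary(fit)
#> GCGMM segmentation summary
#>   gamma = 0.443 (omega = 0.60, tau = 0.75)
#>   volumes (mm^3): fused 893.0, GC consensus 3413.0, GMM 1903.0
#>   mixture sizes: tumour 4, background 4
#>   GrowCut sweeps per feature image: 22, 25, 24, 26, 34, 31, 32, 27

seg_scores(fit$mask, case$truth_mask, case$spec$spacing_mm)
#> DSC 0.938 | mSD 0.51 mm | HD95 2.83 mm | |VR| 0.124
```

Here the loose ROI makes plain GrowCut over-segment heavily (consensus
3413 mm³ against 789 mm³ of truth) and the GMM alone over-segments
moderately; the confidence fusion recovers a mask within 12% of the true
volume at Dice 0.94. `run_study()` repeats this over a simulated cohort
for all three input variants and all three methods (GCGMM, the GrowCut
consensus, FCM), returning score/feature tables, reproducibility and ICC
reports, and the classification stage.

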