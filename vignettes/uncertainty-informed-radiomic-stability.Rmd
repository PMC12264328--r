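---
title: "Uncertainty-informed radiomic stability: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Uncertainty-informed radiomic stability: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(radstab)
```

## The problem

Radiomic features — quantitative intensity, shape and texture descriptors
computed inside a region of interest — are only useful when they are stable.
Two sources of variability dominate in practice: *segmentation variability*
(different delineations of the same scan yield different feature values) and
*scan-rescan variability* (repeated acquisitions of the same subject, with
repositioning, yield different values). `radstab` implements a pipeline that
asks whether restricting feature extraction to *confidently segmented*
regions — defined from the replicate-to-replicate agreement of a stochastic
segmentation model such as a Monte-Carlo-dropout or test-time-augmentation
ensemble — improves feature reproducibility (against segmentation
variability) and repeatability (against scan-rescan variability), and
whether the stable features still discriminate patient groups (here labelled
CKD vs HC, after the kidney-MRI setting the pipeline is designed around).

Because the pipeline's statistical machinery is independent of any particular
dataset or network, the package ships a synthetic cohort generator that
reproduces the *structure* of such a study — two groups with shape/texture
differences, repeated repositioned acquisitions, and per-scan stacks of T
probabilistic segmentation replicates — so every stage is testable without
imaging data or a trained model.

## The uncertainty core

Given a stack of T per-voxel foreground probabilities $p_{it}$, the mean
prediction is $\bar p_i = \tfrac1T\sum_t p_{it}$, binarized at 0.5 into the
mean-prediction (MP) mask; a voxel exactly at 0.5 maps to foreground so the
rule is deterministic. Predictive uncertainty decomposes as

$$U_i^{pred} = U_i^{aleat} + U_i^{epist}
  = \tfrac1T\sum_t p_{it}(1-p_{it}) + \tfrac1T\sum_t (p_{it}-\bar p_i)^2 .$$

The variance term uses the population (1/T) normalization, exactly as the
decomposition is usually printed, not 1/(T−1). An algebraic consequence worth
knowing (and asserted in the tests to 1e−12) is
$U_i^{pred} = \bar p_i (1-\bar p_i)$, which also bounds it by 0.25.

Confidence-level masks CL~th~ are built by first classifying every replicate
voxelwise at 0.5 (the cutoff is configurable; the convention that replicates
are *classified* before voting is a design choice) and then keeping voxels
labelled foreground by at least th% of the T replicates, for th in
10, 20, …, 100. The masks nest: CL~100~ ⊆ … ⊆ CL~10~.

Two loss functions are provided as pure functions (no training happens in
this package): the soft Dice loss and its calibration-aware variant in which
the false-positive term $p_i(1-y_i)$ and false-negative term $(1-p_i)y_i$
are raised to a focal exponent $\gamma$. At $\gamma = 1$ the variant reduces
exactly to the soft Dice loss. Both carry an additive smoothing constant
$\varepsilon = 10^{-6}$ in numerator and denominator so that the all-empty
case is defined (loss 0); this is standard soft-Dice practice.

Segmentation accuracy is scored by the 3-D Dice coefficient between the MP
mask and the ground truth (two empty masks score 1 by convention).
Uncertainty *quality* is scored by the KL divergence between the histogram of
predictive uncertainty at incorrectly classified voxels and the histogram at
correctly classified voxels: a model whose uncertainty flags its own errors
scores high. Histograms use 20 bins over the pooled range, one Laplace count
per bin, and natural logarithms; none of these is canonical, so they are
package choices and configurable. A volume with no misclassified voxels has
no error distribution; the function signals an undefined-divergence
condition rather than returning 0, because "no errors" and "uncertainty does
not separate errors" are different findings.

## Feature extraction

The extractor produces a pinned roster of exactly 105 features across seven
families: 14 three-dimensional shape descriptors, 18 first-order statistics,
and texture features from the GLCM (22), GLRLM (16), GLSZM (16), GLDM (14)
and NGTDM (5) matrices. The roster is fixed by `feature_manifest()` so the
count is testable and stable. Within the standard 24-feature GLCM family,
SumAverage is omitted because it is linearly dependent on JointAverage for a
symmetric matrix, and MCC is omitted as the one feature whose cost is out of
proportion to its use; that trims the total to 105.

Preprocessing follows the common radiomics protocol: resample image and mask
to a target spacing of (1.458, 1.458, 5.5) mm — trilinear for the image,
nearest-neighbour for the mask — then z-score standardize intensities and
discretize to a fixed 64-bin count. Two points were genuinely open and are
resolved as follows:

* **Slice-wise extraction.** Because the slice thickness is large compared to
  the in-plane resolution, intensity and texture features are computed per
  2-D slice intersecting the mask and averaged, unweighted, over contributing
  slices; slices with an empty intersection contribute nothing.
  Discretization happens per slice over that slice's ROI range, making each
  slice a self-contained extraction. *Shape* features, by contrast, are
  computed once on the 3-D mask: a 14-feature shape roster and properties
  such as "volume scales 8-fold under isotropic 2× scaling" are inherently
  three-dimensional, and averaging per-slice contours would not produce a
  volume in mm³.
* **z-score scope.** Standardization statistics come from the whole resampled
  volume, not the ROI, so that the same image transform is shared by every
  mask source for a scan; feature differences between mask sources then
  reflect the masks only. ROI-scoped standardization is available via
  `normalization_scope = "roi"`.

Geometry is computed from voxel data directly: volumes by marching-squares
areas of the 0.5-isocontour per slice times the slice thickness
(`MeshVolume`) and by voxel counting (`VoxelVolume`); surface area by
exposed-face counting, which is systematically larger than a smooth-mesh
estimate (a staircase surface) but consistent across masks, so ratios and
stability comparisons are unaffected; axis lengths from a PCA of voxel
centre coordinates. Degenerate ROIs (e.g. a single voxel) return `NA` for
features that are undefined there, with a warning — never a silent zero.

The image-intensity windowing transform (`intensity_window()`) clamps to
[μ − 0.5σ, μ + 4σ] with population statistics and rescales the clamped range
to [0, 255]; it reproduces the preprocessing a segmentation network would
see and is applied upstream of the radiomics protocol.

## Stability analysis

Reproducibility against segmentation variability is measured per feature by
the average-measure consistency ICC, ICC(3,k) = (MS~R~ − MS~E~)/MS~R~, with
the scans of one group as rows and {ground-truth features, method features}
as the two columns. Repeatability against scan-rescan variability is the
average-measure absolute-agreement ICC,
ICC(2,k) = (MS~R~ − MS~E~)/(MS~R~ + (MS~C~ − MS~E~)/n), with subjects as rows
and the repeated acquisitions as columns, both groups pooled so the design
has enough rows. Both are computed from two-way ANOVA mean squares written
out explicitly; the tests verify them against `stats::aov` to 1e−10.
Negative ICCs are returned as-is; a degenerate decomposition (zero
between-row variance) yields `NA`, which downstream counts as below any
cutoff — a conservative rule that keeps the class partition exact. The row
unit for the consistency ICC (individual scans rather than subject means)
is a package choice; using subject means would discard the within-subject
replication.

Features are then classified with an inclusive 0.8 cutoff on both ICCs:
class 1 (both), class 2 (consistency only), class 3 (agreement only),
class 4 (neither). Scanning th over the confidence levels yields class
counts per threshold and group; the optimal threshold minimizes the class-4
count, breaking ties by the class-1 count and remaining ties by the smallest
threshold (the last rule is ours, for determinism).

Method comparisons use a paired two-tailed Wilcoxon signed-rank test over
the per-feature ICC values. Zero differences are handled by the Pratt
policy — ranked with the rest, then dropped from the statistic — because
discarding them outright (the R default) overstates significance when many
features are unchanged. The null is exact when there are no zeros and
n ≤ 25, otherwise a normal approximation with continuity and Pratt
corrections; an all-zero difference vector is reported as degenerate with
p = 1.

## Group discrimination

The classifier stage restricts the feature table to features repeatable
against scan-rescan variability (classes 1 ∪ 3 at the method's optimal
threshold, required in both groups), drops zero-variance columns and columns
with |Pearson r| > 0.8 against `shape_MeshVolume` (volume itself is kept and
remains a candidate when repeatable), and selects five features by greedy
mRMR aggregated over 500 class-stratified bootstrap resamples. The mRMR
score is relevance minus redundancy, with relevance the class F-statistic
mapped through F/(1+F) onto [0, 1] and redundancy the *maximum* absolute
correlation with the already-selected set. The maximum (rather than the
mean) matters: with mean redundancy, a near-duplicate of a selected feature
regains ground as more uncorrelated features are selected, because its
penalty is diluted by 1/|selected|; the maximum keeps an exact duplicate
excluded no matter when it is reconsidered. The final five are the most
frequently selected across bootstraps, ties broken by mean selection
position and then name, making the selection deterministic given the seed.

Evaluation is leave-one-patient-out: each fold holds out all scans of one
patient, features are standardized with training-fold statistics only, and a
logistic regression is fit; when the fold is separable (coefficients
diverge) the fit falls back to a small fixed ridge penalty (`glmnet`,
α = 0, λ = 0.01) so every fold yields finite probabilities. Held-out
predictions are pooled into a single scan-level ROC; the AUC is the
Mann-Whitney statistic of the pooled predictions. Worth knowing: under a
permutation null, leave-one-out logistic AUCs are biased *below* 0.5 (the
training set shifts away from the held-out label); the tests bound this
bias rather than pretending it away. Competing methods are compared with a
two-sided DeLong test for correlated ROC curves using the placement-value
covariance estimator; its type-I error is verified by simulation.

## The synthetic cohort generator

`simulate_cohort()` builds, per subject, two ellipsoidal "kidneys" with
per-subject random semi-axes on a coronal-like grid, a textured interior
(band-limited Gaussian noise with 4 mm correlation length plus a
low-frequency intensity gradient) over a darker textured background.
Repeats share the anatomy and differ by a rigid in-plane shift and small
rotation followed by resampling, plus an independent white-noise draw —
repositioning is modelled as the sole source of scan-rescan variability.
The group label scales object volume (default −20% for the CKD-labelled
group) and texture-noise amplitude (default +30%), so both shape and
texture carry group signal.

`simulate_prob_stack()` emulates a stochastic segmentation model. The base
probability is a sigmoid of the signed Euclidean distance to the
(bias-shifted) ground-truth boundary with scale `band_width`/4, so
probabilities are ≈0 or ≈1 outside a band of roughly `band_width` around
the contour. Each replicate perturbs the boundary by a smooth Gaussian
random displacement field (correlation length `jitter_scale`, SD
`replicate_jitter`) — the choice of field family is a stand-in, not
data-derived. The `calibration` parameter couples uncertainty to error
location: below 1, an uncertainty patch is placed once per scan away from
the boundary (at least two band widths from it) and applied to each
replicate with probability 1 − `calibration`, shrinking |p − 0.5| without
letting any voxel cross 0.5 — extra uncertainty exactly where the model is
*not* wrong, which is what miscalibration means here. The patch location is
fixed per scan because a miscalibrated model is consistently uncertain
about the same wrong regions; redrawing it per replicate would average the
effect away.

Default conditions mirror the acquisition design the pipeline targets: five
subjects per group, five repeats, T = 50 replicates, a 10×64×64 grid at
(1.458, 1.458, 5.5) mm so the default radiomics resample is an identity,
2 mm repositioning shifts and 2° rotations. What the generator does *not*
emulate: MRI physics and artefacts, anatomically realistic kidneys
(pelvis, cortex/medulla contrast), inter-observer manual-segmentation
variability, and any spatial error structure of a real trained network.
Passing tests therefore demonstrate that the *statistical machinery* behaves
correctly under the assumed structure, not that any particular network's
masks are stable on real MRI.

## Problem sizes and numerical choices

The test suite and the acceptance script run the full pipeline on a
scaled-down cohort: 10 subjects × 5 repeats, T = 20 replicates, an
8×48×48-voxel grid, and a model profile with voxel-scale boundary
variability (band 4 mm, jitter 2.5 mm, bias 1 mm; MP-mask Dice ≈ 0.95).
That profile is deliberate: with sub-voxel jitter the replicate stacks
degenerate to a near-deterministic model, the MP and confidence masks
coincide, and the comparison between them measures nothing. With it, the two
directional findings the pipeline is built around — more scan-rescan
repeatable features at the optimal confidence level than from
mean-prediction masks, and higher error/correct KL separability for a
calibrated than for a miscalibrated profile — hold across independent seeds.

Other numerical conventions collected in one place: mean-prediction and
replicate classification ties map to foreground; Dice smoothing
ε = 1e−6; KL histograms 20 bins, Laplace smoothing 1, natural log; ICC
cutoff 0.8, inclusive; undefined ICCs count below cutoff; empty derived
masks yield NA feature rows (with a warning naming the scan) rather than
aborting a cohort run; the optimal-threshold tie-break ends at the smallest
threshold; bootstrap resamples are stratified by class.

## Limitations

The feature definitions follow the common IBSI-style formulations but are
this package's own implementations; users comparing absolute feature values
against another engine should expect small systematic differences (surface
area in particular, by construction). Confidence-level masks assume the
replicate stack is exchangeable; TTA-style replicates that were not
inverse-transformed back to a common frame violate that. The discrimination
stage is scan-level; per-subject aggregation of predictions is a reasonable
alternative the package does not currently implement.
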