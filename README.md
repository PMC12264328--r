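# radstab

Radiomic feature stability under segmentation uncertainty.

Radiomic analyses extract quantitative intensity, shape and texture features
from a segmented region of interest, and their clinical value hinges on two
kinds of stability: **reproducibility** against segmentation variability
(does a different delineation of the same scan give the same feature?) and
**repeatability** against scan–rescan variability (does a repeated,
repositioned acquisition of the same subject give the same feature?).
Stochastic segmentation models — Monte-Carlo dropout or test-time
augmentation ensembles — produce T probabilistic masks per scan instead of
one, and the disagreement among those replicates localizes where the
segmentation is uncertain. `radstab` implements the full pipeline for asking
whether restricting feature extraction to confidently segmented regions
improves stability, and whether the stable features still discriminate
patient groups. It is aimed at quantitative-imaging researchers who have (or
want to simulate) replicate segmentation stacks.

## What it computes

Starting from a stack of per-voxel probabilities `p_it` (replicate *t*,
voxel *i*):

- **Mean prediction & uncertainty** — `p̄_i = (1/T) Σ_t p_it`, binarized into
  the MP mask, and the decomposition
  `U_i^pred = (1/T) Σ p_it (1 − p_it) + (1/T) Σ (p_it − p̄_i)²`
  (aleatoric + epistemic; exactly `p̄_i(1 − p̄_i)`).
- **Confidence-level masks** — `CL_th` keeps voxels labelled foreground by at
  least `th`% of the classified replicates, for `th` = 10, …, 100; the masks
  nest.
- **Losses & metrics** — soft Dice loss and its focal (`γ`-exponent)
  calibration-aware variant; 3-D Dice overlap; KL divergence between the
  predictive-uncertainty histograms of misclassified vs correctly classified
  voxels.
- **105 radiomic features** — a pinned roster (14 3-D shape, 18 first-order,
  22 GLCM, 16 GLRLM, 16 GLSZM, 14 GLDM, 5 NGTDM), extracted slice-wise with
  unweighted averaging after resampling to (1.458, 1.458, 5.5) mm, z-score
  standardization and 64-bin discretization.
- **Stability classes** — per feature, the average-measure consistency ICC
  `ICC(3,k) = (MS_R − MS_E)/MS_R` against ground-truth masks and the
  absolute-agreement ICC
  `ICC(2,k) = (MS_R − MS_E)/(MS_R + (MS_C − MS_E)/n)` across repeats;
  four classes at an inclusive 0.8 cutoff; a scan over confidence levels
  selects `th_opt` (fewest class-4 features, ties by most class-1); paired
  Wilcoxon signed-rank comparisons between methods.
- **Group discrimination** — zero-variance and volume-correlation filtering,
  bootstrapped mRMR selection of five features, leave-one-patient-out
  logistic regression, pooled ROC/AUC and DeLong tests.
- **Synthetic cohorts** — `simulate_cohort()` and `simulate_prob_stack()`
  generate two-group cohorts with repositioned repeats and replicate stacks
  with controllable boundary band, jitter, bias and calibration, so the whole
  pipeline runs without imaging data.

## Worked example

```r
library(radstab)

cfg <- run_config(
  cohort   = cohort_params(n_per_group = 3, n_repeats = 3,
                           grid_shape = c(8, 48, 48), seed = 42),
  profiles = list(mcd_like = model_profile(band_width = 4, replicate_jitter = 2.5,
                                           calibration = 1, bias = 1)),
  T_rep = 15, seed = 42
)
run <- run_pipeline(cfg, n_boot = 100)
run
#> <radstab_run> 1 profile(s)
#>   mcd_like: mean DSC_3D 0.946, mean KL 3.222, th_opt [CKD=80, HC=80], 34 repeatable, AUC 1

glance(run$profiles$mcd_like$threshold_scan)
#> # A tibble: 2 × 6
#>   group th_opt    n1    n2    n3    n4
#>   <chr>  <dbl> <int> <int> <int> <int>
#> 1 CKD       80    18    66    16     5
#> 2 HC        80    28    49     6    22
```

Reading the output: the simulated stochastic model segments with a mean 3-D
Dice of 0.946 against ground truth, and its predictive uncertainty separates
its own errors from correct voxels with a KL divergence of 3.22 nats. The
threshold scan picks confidence level 80 for both groups: at `CL_80`, only 5
(CKD) and 22 (HC) of the 105 features are in class 4 (neither reproducible
nor repeatable), and 34 features are scan-rescan repeatable in both groups.
The classifier built on those repeatable features separates the two
simulated groups perfectly (AUC = 1 — the injected volume/texture effects
are deliberately strong at this toy size), selecting
`shape_MajorAxisLength`, `shape_MeshVolume`, `shape_Flatness`,
`firstorder_Median` and `shape_Maximum2DDiameterSlice`.

`autoplot()` methods draw the class-count bar chart across thresholds
(`threshold_scan`) and the pooled ROC curve (`lopo_report`); `tidy()` returns
the underlying per-feature and per-scan tibbles. Pipeline runs can also be
driven from a YAML file via `run_config_from_yaml()`, and images, masks and
replicate stacks can be exchanged as NIfTI via `write_cohort_nifti()` /
`read_volume_nifti()`.

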