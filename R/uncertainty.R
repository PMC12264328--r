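# Uncertainty core: mean prediction, aleatoric/epistemic/predictive
# decomposition, confidence-level masks, Dice score/losses, and the KL
# uncertainty-separability metric.

check_stack <- function(stack) {
  if (!(is.array(stack) && length(dim(stack)) == 4L)) {
    abort("a probability stack must be a 4-D array (H, W, slices, T)",
          class = "radstab_input_error")
  }
  if (dim(stack)[4] < 2L) abort("a probability stack needs T >= 2 replicates",
                                class = "radstab_input_error")
  check_probability(stack, "stack probabilities")
  invisible(TRUE)
}

#' Voxelwise mean prediction of a replicate stack
#'
#' The mean probability over the T replicates, binarized voxelwise to a mean
#' prediction (MP) mask. A voxel exactly at the threshold maps to foreground.
#'
#' @param stack 4-D `prob_stack` array `(H, W, slices, T)`.
#' @param binarize_at probability cutoff (default 0.5).
#' @return list with `pbar` (mean probability volume) and `mp_mask`
#'   (binary volume), both carrying the stack's spacing.
#' @export
mean_prediction <- function(stack, binarize_at = 0.5) {
  check_stack(stack)
  sp <- spacing_of(stack)
  d <- dim(stack)
  pbar <- rowMeans(matrix(stack, prod(d[1:3]), d[4]))
  pbar <- with_spacing(array(pbar, d[1:3]), sp)
  list(pbar = pbar, mp_mask = with_spacing((pbar >= binarize_at) * 1, sp))
}

#' Decompose predictive uncertainty into aleatoric and epistemic parts
#'
#' Per voxel, aleatoric = mean over replicates of `p(1 - p)`, epistemic =
#' population variance of the replicate probabilities, predictive = their sum
#' (which equals `pbar * (1 - pbar)` exactly).
#'
#' @param stack 4-D `prob_stack` array.
#' @return list of volumes `aleatoric`, `epistemic`, `predictive`.
#' @export
uncertainty_decompose <- function(stack) {
  check_stack(stack)
  sp <- spacing_of(stack)
  d <- dim(stack)
  M <- matrix(stack, prod(d[1:3]), d[4])
  pbar <- rowMeans(M)
  aleat <- rowMeans(M * (1 - M))
  epist <- rowMeans((M - pbar)^2)
  list(aleatoric = with_spacing(array(aleat, d[1:3]), sp),
       epistemic = with_spacing(array(epist, d[1:3]), sp),
       predictive = with_spacing(array(aleat + epist, d[1:3]), sp))
}

#' Confidence-level masks from a replicate stack
#'
#' Each replicate is first classified voxelwise (`p >= classify_at`); a voxel
#' belongs to the mask `CL_th` when at least `th`% of the T replicates classify
#' it as foreground. Masks are nested: `CL_100` is contained in every lower
#' level.
#'
#' @param stack 4-D `prob_stack` array.
#' @param thresholds confidence levels in percent, each in `(0, 100]`.
#' @param classify_at per-replicate classification cutoff (default 0.5).
#' @return list with `vote_fraction` (volume of per-voxel foreground vote
#'   fractions) and `masks`, a named list `CL_10`, ... of binary volumes.
#' @export
confidence_masks <- function(stack, thresholds = seq(10, 100, by = 10),
                             classify_at = 0.5) {
  check_stack(stack)
  if (any(thresholds <= 0 | thresholds > 100)) {
    abort("confidence thresholds must lie in (0, 100]", class = "radstab_parameter_error")
  }
  sp <- spacing_of(stack)
  d <- dim(stack)
  votes <- rowMeans(matrix(stack, prod(d[1:3]), d[4]) >= classify_at)
  vf <- with_spacing(array(votes, d[1:3]), sp)
  masks <- lapply(thresholds, function(th) with_spacing((100 * vf >= th) * 1, sp))
  names(masks) <- sprintf("CL_%d", as.integer(thresholds))
  list(vote_fraction = vf, masks = masks)
}

#' Dice similarity coefficient between two binary masks
#'
#' `2|A ∩ B| / (|A| + |B|)`; two empty masks score 1 by convention.
#'
#' @param pred_mask,gt_mask binary arrays on the same grid.
#' @return similarity in `[0, 1]`.
#' @export
dice_score <- function(pred_mask, gt_mask) {
  check_same_grid(pred_mask, gt_mask, "masks")
  check_binary(pred_mask, "pred_mask"); check_binary(gt_mask, "gt_mask")
  a <- sum(pred_mask > 0); b <- sum(gt_mask > 0)
  if (a + b == 0) return(1)
  2 * sum(pred_mask > 0 & gt_mask > 0) / (a + b)
}

DICE_EPS <- 1e-6

#' Soft Dice loss
#'
#' `1 - 2*sum(p*y) / (sum(p) + sum(y))` with an additive smoothing constant in
#' numerator and denominator so the all-empty case is defined (loss 0).
#'
#' @param pred_prob probability grid in `[0, 1]`.
#' @param gt binary grid on the same lattice.
#' @param eps smoothing constant.
#' @return loss value `>= 0`.
#' @export
dice_loss <- function(pred_prob, gt, eps = DICE_EPS) {
  check_same_grid(pred_prob, gt, "grids")
  check_probability(pred_prob, "predictions")
  check_binary(gt, "gt")
  1 - (2 * sum(pred_prob * gt) + eps) / (sum(pred_prob) + sum(gt) + eps)
}

#' Calibration-aware Dice loss with a focal exponent
#'
#' Like the soft Dice loss but the false-positive term `p*(1-y)` and the
#' false-negative term `(1-p)*y` are raised to a focal exponent `gamma`,
#' which penalizes overconfident errors; `gamma = 1` recovers the plain Dice
#' loss exactly.
#'
#' @inheritParams dice_loss
#' @param gamma focal exponent, `> 0`.
#' @return loss value `>= 0`.
#' @export
dice_plus_loss <- function(pred_prob, gt, gamma = 2, eps = DICE_EPS) {
  if (gamma <= 0) abort("gamma must be > 0", class = "radstab_parameter_error")
  check_same_grid(pred_prob, gt, "grids")
  check_probability(pred_prob, "predictions")
  check_binary(gt, "gt")
  tp2 <- 2 * sum(pred_prob * gt)
  fp <- sum((pred_prob * (1 - gt))^gamma)
  fn <- sum(((1 - pred_prob) * gt)^gamma)
  1 - (tp2 + eps) / (tp2 + fp + fn + eps)
}

# Histogram KL kernel: normalized counts with Laplace smoothing, natural log.
kl_from_counts <- function(cp, cq) {
  p <- (cp + 1) / sum(cp + 1)
  q <- (cq + 1) / sum(cq + 1)
  sum(p * log(p / q))
}

#' KL-divergence separability of uncertainty at errors vs correct voxels
#'
#' Compares the distribution of predictive uncertainty at incorrectly
#' classified voxels against the distribution at correctly classified voxels:
#' histograms share bin edges over the pooled range (`n_bins` bins, one
#' Laplace count added per bin) and the returned value is
#' `KL(incorrect || correct)` in nats. High values mean the model's
#' uncertainty flags its own errors.
#'
#' @param predictive volume of per-voxel predictive uncertainty.
#' @param pred_mask,gt_mask aligned binary masks defining correctness.
#' @param n_bins histogram bin count (default 20).
#' @return divergence `>= 0` (nats).
#' @export
kl_uncertainty_separability <- function(predictive, pred_mask, gt_mask, n_bins = 20) {
  check_same_grid(predictive, pred_mask, "grids")
  check_same_grid(predictive, gt_mask, "grids")
  correct <- (pred_mask > 0) == (gt_mask > 0)
  if (all(correct)) {
    abort("no incorrectly classified voxels: KL separability is undefined",
          class = "radstab_undefined_divergence")
  }
  if (!any(correct)) {
    abort("no correctly classified voxels: KL separability is undefined",
          class = "radstab_undefined_divergence")
  }
  u <- as.vector(predictive)
  rng <- range(u)
  if (rng[1] == rng[2]) rng <- rng + c(-0.5, 0.5) * 1e-8
  breaks <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  ci <- pmin(pmax(findInterval(u, breaks, rightmost.closed = TRUE), 1L), n_bins)
  c_inc <- tabulate(ci[!correct], nbins = n_bins)
  c_cor <- tabulate(ci[correct], nbins = n_bins)
  kl_from_counts(c_inc, c_cor)
}
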