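# Synthetic cohort generator: bilateral ellipsoidal "kidneys" with textured
# interiors, scan-rescan repositioning, and stochastic segmentation replicates
# with controllable boundary uncertainty and calibration.

#' Parameters of a synthetic cohort
#'
#' @param n_per_group subjects per group (CKD and HC).
#' @param n_repeats repeated acquisitions per subject (repositioning between).
#' @param grid_shape integer length-3 `(slices, height, width)` in voxels.
#' @param spacing voxel spacing `(x, y, z)` mm; default matches a common
#'   coronal T2 acquisition grid so the radiomics resample is an identity.
#' @param group_effects list with `volume` (relative shift of mean object
#'   volume in the CKD group, e.g. `-0.2` for 20% smaller) and `texture`
#'   (relative shift of texture-noise amplitude).
#' @param reposition_sigma SD (mm) of the rigid in-plane shift between repeats.
#' @param reposition_rot_sigma SD (degrees) of the in-plane rotation between
#'   repeats.
#' @param noise_sigma SD of additive white intensity noise per acquisition.
#' @param seed random seed; the same seed yields a bit-identical cohort.
#' @return a `cohort_params` list.
#' @export
cohort_params <- function(n_per_group = 5, n_repeats = 5,
                          grid_shape = c(10, 64, 64),
                          spacing = c(1.458, 1.458, 5.5),
                          group_effects = list(volume = -0.2, texture = 0.3),
                          reposition_sigma = 2, reposition_rot_sigma = 2,
                          noise_sigma = 5, seed = 1) {
  if (n_per_group < 1) abort("n_per_group must be >= 1", class = "radstab_parameter_error")
  if (n_repeats < 2) abort("n_repeats must be >= 2", class = "radstab_parameter_error")
  if (reposition_sigma < 0 || reposition_rot_sigma < 0 || noise_sigma < 0) {
    abort("all sigmas must be >= 0", class = "radstab_parameter_error")
  }
  stopifnot(length(grid_shape) == 3L, all(grid_shape >= 4), length(spacing) == 3L,
            all(spacing > 0))
  structure(list(
    n_per_group = as.integer(n_per_group), n_repeats = as.integer(n_repeats),
    grid_shape = as.integer(grid_shape), spacing = as.numeric(spacing),
    group_effects = group_effects, reposition_sigma = reposition_sigma,
    reposition_rot_sigma = reposition_rot_sigma, noise_sigma = noise_sigma,
    seed = as.integer(seed)
  ), class = "cohort_params")
}

#' Behaviour profile of a stochastic segmentation model
#'
#' Controls how simulated segmentation replicates disagree with each other and
#' with the ground truth, so that dropout-like, augmentation-like and
#' calibrated/miscalibrated model behaviours can be imitated.
#'
#' @param band_width spatial width (mm) of the uncertain boundary band.
#' @param replicate_jitter SD (mm) of the smooth per-replicate contour
#'   perturbation (drives epistemic spread).
#' @param calibration in `[0, 1]`: 1 concentrates uncertainty where replicates
#'   disagree with the truth; 0 scatters extra uncertainty patches away from
#'   true errors.
#' @param bias systematic over-/under-segmentation offset (mm; positive
#'   enlarges the predicted object).
#' @param jitter_scale correlation length (mm) of the smooth perturbation field.
#' @return a `model_profile` list.
#' @export
model_profile <- function(band_width = 3, replicate_jitter = 1.5,
                          calibration = 1, bias = 0, jitter_scale = 10) {
  if (band_width <= 0) abort("band_width must be > 0", class = "radstab_parameter_error")
  if (replicate_jitter < 0) abort("replicate_jitter must be >= 0", class = "radstab_parameter_error")
  if (calibration < 0 || calibration > 1) {
    abort("calibration must lie in [0, 1]", class = "radstab_parameter_error")
  }
  structure(list(band_width = band_width, replicate_jitter = replicate_jitter,
                 calibration = calibration, bias = bias,
                 jitter_scale = jitter_scale),
            class = "model_profile")
}

# Smooth Gaussian random field: white noise on a coarse grid (one node per
# `scale_mm`), trilinearly upsampled, rescaled to unit SD then multiplied by sd.
smooth_field <- function(dim3, spacing, scale_mm, sd) {
  if (sd == 0) return(array(0, dim3))
  nc <- pmax(2L, as.integer(ceiling(dim3 * spacing / scale_mm)) + 1L)
  coarse <- array(rnorm(prod(nc)), nc)
  # upsample to the target grid by sampling fractional coarse indices directly
  idx <- lapply(1:3, function(a) seq(1, nc[a], length.out = dim3[a]))
  g <- function(ii, jj, kk) {
    out <- coarse[ii, jj, kk, drop = FALSE]; dim(out) <- dim3; out
  }
  clamp <- function(x, n) pmin(pmax(x, 1), n)
  i0 <- clamp(floor(idx[[1]]), nc[1]); i1 <- clamp(i0 + 1, nc[1]); fi <- idx[[1]] - i0
  j0 <- clamp(floor(idx[[2]]), nc[2]); j1 <- clamp(j0 + 1, nc[2]); fj <- idx[[2]] - j0
  k0 <- clamp(floor(idx[[3]]), nc[3]); k1 <- clamp(k0 + 1, nc[3]); fk <- idx[[3]] - k0
  wi <- array(fi, dim3)
  wj <- aperm(array(fj, dim3[c(2, 1, 3)]), c(2, 1, 3))
  wk <- aperm(array(fk, dim3[c(3, 1, 2)]), c(2, 3, 1))
  A <- (1 - wi) * ((1 - wj) * ((1 - wk) * g(i0, j0, k0) + wk * g(i0, j0, k1)) +
                     wj * ((1 - wk) * g(i0, j1, k0) + wk * g(i0, j1, k1))) +
    wi * ((1 - wj) * ((1 - wk) * g(i1, j0, k0) + wk * g(i1, j0, k1)) +
            wj * ((1 - wk) * g(i1, j1, k0) + wk * g(i1, j1, k1)))
  s <- sd(as.vector(A))
  if (s == 0) return(array(0, dim3))
  A / s * sd
}

# Two ellipsoids ("kidneys") on the voxel grid; axes in mm, centres in voxel
# fractions of the field of view.
ellipsoid_pair_mask <- function(dim_hws, spacing, semi_axes, centre_frac_cols = c(0.3, 0.7)) {
  H <- dim_hws[1]; W <- dim_hws[2]; S <- dim_hws[3]
  y <- (seq_len(H) - 0.5) * spacing[1]
  x <- (seq_len(W) - 0.5) * spacing[2]
  z <- (seq_len(S) - 0.5) * spacing[3]
  Y <- array(y, c(H, W, S))
  X <- aperm(array(x, c(W, H, S)), c(2, 1, 3))
  Z <- aperm(array(z, c(S, H, W)), c(2, 3, 1))
  cy <- H * spacing[1] / 2; cz <- S * spacing[3] / 2
  m <- array(FALSE, c(H, W, S))
  for (fc in centre_frac_cols) {
    cx <- W * spacing[2] * fc
    m <- m | (((Y - cy) / semi_axes[1])^2 + ((X - cx) / semi_axes[2])^2 +
                ((Z - cz) / semi_axes[3])^2 <= 1)
  }
  m
}

#' Simulate a synthetic scan-rescan cohort
#'
#' Each subject has a fixed base anatomy (two textured ellipsoidal objects);
#' repeats share the anatomy but differ by a rigid in-plane repositioning and
#' an independent intensity-noise draw. The group label modulates object
#' volume and texture-noise amplitude per `group_effects`.
#'
#' @param params a [cohort_params()] object.
#' @return a tibble with one row per acquisition: `subject_id`, `group`
#'   (`"CKD"`/`"HC"`), `repeat_index`, and list-columns `image` and `gt_mask`
#'   (3-D arrays with spacing attributes).
#' @export
simulate_cohort <- function(params) {
  if (!inherits(params, "cohort_params")) params <- do.call(cohort_params, params)
  gs <- params$grid_shape                   # (slices, H, W)
  dim_hws <- c(gs[2], gs[3], gs[1])
  sp <- params$spacing
  base_axes <- c(0.22 * dim_hws[1] * sp[1], 0.13 * dim_hws[2] * sp[2] / 2,
                 0.28 * dim_hws[3] * sp[3])
  vol_shift <- params$group_effects$volume %||% 0
  tex_shift <- params$group_effects$texture %||% 0
  rows <- withr::with_seed(params$seed, {
    subj <- 0L
    out <- list()
    for (grp in c("CKD", "HC")) {
      vol_factor <- if (grp == "CKD") (1 + vol_shift)^(1 / 3) else 1
      tex_amp <- 12 * (if (grp == "CKD") 1 + tex_shift else 1)
      for (s in seq_len(params$n_per_group)) {
        subj <- subj + 1L
        axes <- base_axes * vol_factor * exp(rnorm(3, 0, 0.04))
        base_mask <- ellipsoid_pair_mask(dim_hws, sp, axes)
        grad_dir <- runif(1, 0, 2 * pi)
        H <- dim_hws[1]; W <- dim_hws[2]; S <- dim_hws[3]
        gy <- matrix((seq_len(H) - H / 2) / H, H, W)
        gx <- matrix((seq_len(W) - W / 2) / W, H, W, byrow = TRUE)
        grad2d <- 15 * (cos(grad_dir) * gy + sin(grad_dir) * gx)
        grad <- array(grad2d, c(H, W, S))
        texture <- smooth_field(dim_hws, sp, scale_mm = 4, sd = tex_amp)
        bg_texture <- smooth_field(dim_hws, sp, scale_mm = 6, sd = 6)
        base_img <- array(40, dim_hws) + bg_texture
        base_img[base_mask] <- 120 + grad[base_mask] + texture[base_mask]
        base_img <- with_spacing(base_img, sp)
        base_mask <- with_spacing(base_mask * 1, sp)
        for (r in seq_len(params$n_repeats)) {
          shift <- rnorm(2, 0, params$reposition_sigma)
          ang <- rnorm(1, 0, params$reposition_rot_sigma)
          img <- rigid_transform(base_img, shift, ang, method = "linear", fill = 40)
          msk <- rigid_transform(base_mask, shift, ang, method = "nearest", fill = 0)
          if (params$noise_sigma > 0) {
            img <- with_spacing(img + array(rnorm(prod(dim_hws), 0, params$noise_sigma),
                                            dim_hws), sp)
          }
          out[[length(out) + 1L]] <- tibble::tibble(
            subject_id = sprintf("S%02d", subj), group = grp, repeat_index = r,
            image = list(img), gt_mask = list(msk)
          )
        }
      }
    }
    out
  })
  res <- dplyr::bind_rows(rows)
  class(res) <- c("radstab_cohort", class(res))
  res
}

#' Simulate a stack of stochastic segmentation replicates for one scan
#'
#' The base foreground probability is a sigmoid of the signed distance to the
#' (optionally bias-shifted) ground-truth boundary with scale
#' `band_width / 4`; each replicate perturbs the boundary by a smooth random
#' displacement field with SD `replicate_jitter`. With probability
#' `1 - calibration` a replicate additionally receives an uncertainty patch
#' placed away from the boundary (uncertainty unrelated to true error),
#' imitating a miscalibrated model.
#'
#' @param record one cohort row (or a list with `image`/`gt_mask`).
#' @param profile a [model_profile()].
#' @param T_rep number of replicates (>= 2).
#' @param seed random seed for the stack.
#' @return a `prob_stack`: 4-D array `(H, W, slices, T)` of probabilities with
#'   a spacing attribute.
#' @export
simulate_prob_stack <- function(record, profile, T_rep = 50, seed = 1) {
  if (T_rep < 2) abort("T_rep must be >= 2", class = "radstab_parameter_error")
  gt <- if (is.data.frame(record)) record$gt_mask[[1]] else record$gt_mask
  sp <- spacing_of(gt)
  d <- signed_distance(gt)
  scale <- profile$band_width / 4
  d3 <- dim(gt)
  stack <- array(0, c(d3, T_rep))
  far <- which(abs(d) > 2 * profile$band_width)
  withr::with_seed(seed, {
    # a miscalibrated model is consistently uncertain about the same wrong
    # region: the patch location is drawn once per scan, not per replicate
    patch_w <- NULL
    if (profile$calibration < 1 && length(far) > 0) {
      centre <- arrayInd(far[sample.int(length(far), 1)], d3)
      H <- d3[1]; W <- d3[2]; S <- d3[3]
      yy <- ((seq_len(H) - centre[1]) * sp[1])^2
      xx <- ((seq_len(W) - centre[2]) * sp[2])^2
      zz <- ((seq_len(S) - centre[3]) * sp[3])^2
      r2 <- outer(outer(yy, xx, "+"), zz, "+")
      patch_w <- 0.95 * exp(-r2 / (2 * 8^2))
    }
    for (t in seq_len(T_rep)) {
      delta <- smooth_field(d3, sp, scale_mm = profile$jitter_scale,
                            sd = profile$replicate_jitter)
      p <- plogis((d + profile$bias + delta) / scale)
      if (!is.null(patch_w) && runif(1) < (1 - profile$calibration)) {
        # shrink |p - 0.5| without crossing 0.5: adds uncertainty, not error
        p <- 0.5 + (p - 0.5) * (1 - patch_w)
      }
      stack[, , , t] <- p
    }
  })
  structure(stack, spacing = sp, class = "prob_stack")
}
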