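# Intensity windowing, resampling and standardization ahead of feature
# extraction.

#' Window intensities to a robust range and rescale to [0, 255]
#'
#' Clamps voxel intensities to `[mu - 0.5*sigma, mu + 4*sigma]` (mu, sigma =
#' mean and population SD over the whole volume), then rescales the clamped
#' range linearly to `[0, 255]`.
#'
#' @param image intensity array (>= 2 voxels).
#' @return windowed array on the same grid; a constant image yields an
#'   all-zero grid with a warning.
#' @export
intensity_window <- function(image) {
  if (length(image) < 2) abort("image must have at least 2 voxels",
                               class = "radstab_input_error")
  mu <- mean(image)
  sigma <- sqrt(mean((image - mu)^2))
  if (sigma == 0) {
    warn("constant image: intensity window is degenerate, returning zeros",
         class = "radstab_degenerate_input")
    out <- array(0, dim(image))
    if (!is.null(attr(image, "spacing"))) out <- with_spacing(out, spacing_of(image))
    return(out)
  }
  lo <- mu - 0.5 * sigma
  hi <- mu + 4 * sigma
  x <- pmin(pmax(image, lo), hi)
  rng <- range(x)
  out <- (x - rng[1]) / (rng[2] - rng[1]) * 255
  attributes(out) <- attributes(image)
  out
}

#' Resample and standardize an image/mask pair for feature extraction
#'
#' Resamples the image to `cfg$target_spacing` (nearest neighbour or
#' trilinear per `cfg$interpolator`) and the mask with nearest neighbour, then
#' z-score standardizes intensities (over the whole volume or the ROI per
#' `cfg$normalization_scope`).
#'
#' @param image intensity volume with spacing.
#' @param mask aligned binary volume.
#' @param cfg a [radiomics_config()].
#' @return list with resampled `image` and `mask`.
#' @export
preprocess_for_radiomics <- function(image, mask, cfg = radiomics_config()) {
  check_same_grid(image, mask, "image and mask")
  img_method <- if (cfg$interpolator >= 1) "linear" else "nearest"
  img <- resample_volume(image, cfg$target_spacing, method = img_method)
  msk <- resample_volume(mask, cfg$target_spacing, method = "nearest")
  if (!any(msk > 0)) {
    abort("mask is empty after resampling", class = "radstab_empty_roi")
  }
  if (isTRUE(cfg$normalization)) {
    ref <- if (cfg$normalization_scope == "roi") img[msk > 0] else as.vector(img)
    s <- sd(ref)
    if (s == 0) s <- 1
    img <- with_spacing(array((img - mean(ref)) / s, dim(img)), cfg$target_spacing)
  }
  list(image = img, mask = msk)
}

# Discretize ROI intensities of one slice to 1..n_bins over the slice-ROI
# min-max range; returns an integer matrix with NA outside the ROI.
discretize_slice <- function(slice, roi, n_bins) {
  v <- slice[roi]
  rng <- range(v)
  out <- matrix(NA_integer_, nrow(slice), ncol(slice))
  if (rng[1] == rng[2]) {
    out[roi] <- 1L
    return(out)
  }
  g <- floor((v - rng[1]) / (rng[2] - rng[1]) * n_bins) + 1L
  g[g > n_bins] <- as.integer(n_bins)
  out[roi] <- g
  out
}
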