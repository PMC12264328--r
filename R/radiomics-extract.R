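# Slice-wise feature extraction and cohort-level feature tables.

#' Extract the pinned radiomic feature vector from one image/mask pair
#'
#' Intensity and texture features are computed per 2-D slice intersecting the
#' mask (discretized to `cfg$n_bins` gray levels over the slice-ROI range) and
#' averaged, unweighted, over contributing slices; the 14 shape features are
#' computed once on the 3-D mask. Inputs are expected to be preprocessed (see
#' [preprocess_for_radiomics()]).
#'
#' @param image intensity volume with spacing.
#' @param mask aligned binary volume (nonempty).
#' @param cfg a [radiomics_config()].
#' @return a named numeric vector following [feature_manifest()] (105 features
#'   for the default configuration). Features undefined for a degenerate ROI
#'   (e.g. a single voxel) are returned as `NA` with a warning.
#' @export
extract_features <- function(image, mask, cfg = radiomics_config()) {
  check_same_grid(image, mask, "image and mask")
  m <- mask > 0
  if (!any(m)) abort("mask is empty", class = "radstab_empty_roi")
  sp <- spacing_of(image, spacing_of(mask))
  vv <- voxel_volume(sp)
  Ng <- cfg$n_bins
  d <- dim(image)
  out <- list()

  if ("shape" %in% cfg$categories) {
    out$shape <- shape_features_3d(m, sp)
  }

  slice_cats <- intersect(cfg$categories,
                          c("firstorder", "glcm", "glrlm", "glszm", "gldm", "ngtdm"))
  if (length(slice_cats)) {
    ks <- which(apply(m, 3, any))
    per_slice <- lapply(ks, function(k) {
      sl <- image[, , k]
      roi <- m[, , k]
      disc <- discretize_slice(sl, roi, Ng)
      dv <- disc[roi]
      res <- list()
      if ("firstorder" %in% slice_cats) res$firstorder <- firstorder_slice(sl[roi], dv, vv)
      if ("glcm" %in% slice_cats) res$glcm <- glcm_features(disc, Ng)
      if ("glrlm" %in% slice_cats) res$glrlm <- glrlm_features(disc, Ng)
      if ("glszm" %in% slice_cats) res$glszm <- glszm_features(disc, Ng)
      if ("gldm" %in% slice_cats) res$gldm <- setNames(gldm_features(disc, Ng), GLDM_NAMES)
      if ("ngtdm" %in% slice_cats) res$ngtdm <- ngtdm_features(disc, Ng)
      unlist(res)
    })
    M <- do.call(rbind, per_slice)
    avg <- colMeans(M)
    names(avg) <- sub("^([a-z]+)\\.", "\\1_", names(avg))
    for (cat in slice_cats) {
      out[[cat]] <- avg[startsWith(names(avg), paste0(cat, "_"))]
      names(out[[cat]]) <- sub(paste0("^", cat, "_"), "", names(out[[cat]]))
    }
  }

  manifest <- feature_manifest(cfg)
  vec <- setNames(rep(NA_real_, length(manifest)), manifest)
  for (cat in names(out)) {
    nm <- paste0(cat, "_", names(out[[cat]]))
    vec[nm] <- unname(out[[cat]])
  }
  if (anyNA(vec)) {
    warn(sprintf("%d features undefined for this ROI (returned as NA)", sum(is.na(vec))),
         class = "radstab_undefined_features")
  }
  vec
}

#' Build a feature table over cohort scans and mask sources
#'
#' For every scan, preprocesses the image once and resamples the ground-truth
#' mask plus every supplied derived mask (mean-prediction and confidence-level
#' masks) onto the same grid, so per-row feature differences reflect the mask
#' choice only.
#'
#' @param cohort tibble from [simulate_cohort()].
#' @param masks optional named list (per scan index) of named lists of extra
#'   binary masks, e.g. `list(MP = ..., CL_10 = ...)`. `NULL` extracts from the
#'   ground truth only.
#' @param cfg a [radiomics_config()].
#' @return tibble keyed by `subject_id`, `group`, `repeat_index`,
#'   `mask_source`, with one column per manifest feature.
#' @export
cohort_feature_table <- function(cohort, masks = NULL, cfg = radiomics_config()) {
  manifest <- feature_manifest(cfg)
  rows <- vector("list", nrow(cohort) * (1 + length(masks[[1]] %||% list())))
  ri <- 0L
  for (s in seq_len(nrow(cohort))) {
    img <- cohort$image[[s]]
    sources <- c(list(GT = cohort$gt_mask[[s]]), masks[[s]] %||% list())
    # whole-volume preprocessing does not depend on the mask: do it once
    shared_img <- if (cfg$normalization_scope == "volume") {
      img_method <- if (cfg$interpolator >= 1) "linear" else "nearest"
      ir <- resample_volume(img, cfg$target_spacing, method = img_method)
      if (isTRUE(cfg$normalization)) {
        s_ <- sd(as.vector(ir)); if (s_ == 0) s_ <- 1
        ir <- with_spacing(array((ir - mean(ir)) / s_, dim(ir)), cfg$target_spacing)
      }
      ir
    } else NULL
    for (nm in names(sources)) {
      fv <- tryCatch({
        if (is.null(shared_img)) {
          pp <- preprocess_for_radiomics(img, sources[[nm]], cfg)
        } else {
          msk <- resample_volume(sources[[nm]], cfg$target_spacing, method = "nearest")
          if (!any(msk > 0)) abort("empty", class = "radstab_empty_roi")
          pp <- list(image = shared_img, mask = msk)
        }
        suppressWarnings(extract_features(pp$image, pp$mask, cfg))
      }, radstab_empty_roi = function(e) {
        warn(sprintf("mask '%s' for subject %s repeat %d is empty: features set to NA",
                     nm, cohort$subject_id[s], cohort$repeat_index[s]),
             class = "radstab_empty_mask_skipped")
        setNames(rep(NA_real_, length(manifest)), manifest)
      })
      ri <- ri + 1L
      rows[[ri]] <- tibble::tibble(
        subject_id = cohort$subject_id[s], group = cohort$group[s],
        repeat_index = cohort$repeat_index[s], mask_source = nm,
        !!!as.list(fv)
      )
    }
  }
  dplyr::bind_rows(rows[seq_len(ri)])
}
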