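# Optional NIfTI exchange (requires the RNifti package).

need_rnifti <- function() {
  if (!requireNamespace("RNifti", quietly = TRUE)) {
    abort("RNifti is required for NIfTI I/O", class = "radstab_missing_dependency")
  }
}

#' Write a volume (or 4-D replicate stack) as NIfTI
#'
#' @param vol 3-D volume or 4-D `prob_stack` (replicates as 4th dimension).
#' @param path output path (`.nii` or `.nii.gz`).
#' @return invisibly, `path`.
#' @export
write_volume_nifti <- function(vol, path) {
  need_rnifti()
  img <- RNifti::asNifti(unclass(vol))
  sp <- spacing_of(vol)
  RNifti::pixdim(img) <- if (length(dim(vol)) == 4L) c(sp, 1) else sp
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a NIfTI volume with spacing
#'
#' @param path NIfTI file.
#' @return array with a `spacing` attribute.
#' @export
read_volume_nifti <- function(path) {
  need_rnifti()
  img <- RNifti::readNifti(path)
  sp <- RNifti::pixdim(img)[seq_len(min(3L, length(dim(img))))]
  if (length(sp) < 3) sp <- c(sp, rep(1, 3 - length(sp)))
  with_spacing(array(as.numeric(img), dim(img)), sp)
}

#' Export a cohort and optional mask sets as NIfTI files
#'
#' Writes one image and one ground-truth mask per scan; confidence-level masks
#' are written one file per threshold with the level embedded in the filename
#' (e.g. `S01_r1_CL080.nii.gz`).
#'
#' @param cohort tibble from [simulate_cohort()].
#' @param dir output directory.
#' @param masks optional per-scan named mask lists (as in
#'   [cohort_feature_table()]).
#' @return invisibly, the written file names.
#' @export
write_cohort_nifti <- function(cohort, dir, masks = NULL) {
  need_rnifti()
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  for (s in seq_len(nrow(cohort))) {
    stem <- sprintf("%s_r%d", cohort$subject_id[s], cohort$repeat_index[s])
    f1 <- file.path(dir, paste0(stem, "_image.nii.gz"))
    f2 <- file.path(dir, paste0(stem, "_gt.nii.gz"))
    write_volume_nifti(cohort$image[[s]], f1)
    write_volume_nifti(cohort$gt_mask[[s]], f2)
    files <- c(files, f1, f2)
    for (nm in names(masks[[s]] %||% list())) {
      tag <- if (startsWith(nm, "CL_")) {
        sprintf("CL%03d", as.integer(sub("CL_", "", nm)))
      } else nm
      f <- file.path(dir, sprintf("%s_%s.nii.gz", stem, tag))
      write_volume_nifti(masks[[s]][[nm]], f)
      files <- c(files, f)
    }
  }
  invisible(files)
}
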