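# 3-D shape descriptors of a binary mask. Volumes/areas come from voxel and
# exposed-face counting (MeshVolume uses a half-voxel boundary correction as a
# surface-mesh estimate); axis lengths from a PCA of voxel centre coordinates.

shape_features_3d <- function(mask, spacing) {
  m <- mask > 0
  d <- dim(m)
  vv <- voxel_volume(spacing)
  n_vox <- sum(m)
  if (n_vox == 0) abort("empty mask has no shape", class = "radstab_empty_roi")

  # exposed faces per axis (including volume border)
  shift_pad <- function(arr, axis, by) {
    idx <- lapply(d, seq_len)
    src <- idx
    out <- array(FALSE, d)
    rng <- seq_len(d[axis] - abs(by))
    if (by > 0) { idx[[axis]] <- rng + by; src[[axis]] <- rng }
    else { idx[[axis]] <- rng; src[[axis]] <- rng + abs(by) }
    out[idx[[1]], idx[[2]], idx[[3]]] <- arr[src[[1]], src[[2]], src[[3]]]
    out
  }
  face_area <- c(spacing[2] * spacing[3], spacing[1] * spacing[3],
                 spacing[1] * spacing[2])
  exposed <- 0
  boundary <- array(FALSE, d)
  for (a in 1:3) {
    for (s in c(-1, 1)) {
      nb <- shift_pad(m, a, s)
      faces <- m & !nb
      exposed <- exposed + sum(faces) * face_area[a]
      boundary <- boundary | faces
    }
  }
  n_bound <- sum(boundary)
  # mesh-style volume: marching-squares area of the 0.5-isocontour per slice,
  # times slice thickness (distinct from plain voxel counting)
  ms_area <- function(sl) {
    P <- matrix(FALSE, nrow(sl) + 2, ncol(sl) + 2)
    P[2:(nrow(sl) + 1), 2:(ncol(sl) + 1)] <- sl
    a <- P[-nrow(P), -ncol(P)]; b <- P[-1, -ncol(P)]
    cc <- P[-nrow(P), -1]; dd <- P[-1, -1]
    cnt <- a + b + cc + dd
    diag2 <- (a & dd & !b & !cc) | (b & cc & !a & !dd)
    area <- numeric(length(cnt))
    area[cnt == 1] <- 0.125
    area[cnt == 2] <- 0.5
    area[cnt == 2 & diag2] <- 0.25
    area[cnt == 3] <- 0.875
    area[cnt == 4] <- 1
    sum(area)
  }
  slice_areas <- vapply(seq_len(d[3]), function(k) ms_area(m[, , k]), numeric(1))
  mesh_vol <- sum(slice_areas) * spacing[1] * spacing[2] * spacing[3]
  vox_vol_total <- n_vox * vv
  sa <- exposed
  sphericity <- (36 * pi * mesh_vol^2)^(1 / 3) / sa

  coords <- which(m, arr.ind = TRUE)
  phys <- cbind((coords[, 1] - 0.5) * spacing[1],
                (coords[, 2] - 0.5) * spacing[2],
                (coords[, 3] - 0.5) * spacing[3])
  bidx <- which(boundary & m, arr.ind = TRUE)
  bphys <- cbind((bidx[, 1] - 0.5) * spacing[1],
                 (bidx[, 2] - 0.5) * spacing[2],
                 (bidx[, 3] - 0.5) * spacing[3])
  # cap the pairwise-distance set for very large surfaces (deterministic thinning)
  if (nrow(bphys) > 3000) {
    keep <- seq(1, nrow(bphys), length.out = 3000)
    bphys <- bphys[unique(as.integer(keep)), , drop = FALSE]
    bidx <- bidx[unique(as.integer(keep)), , drop = FALSE]
  }
  max_pair <- function(P) {
    if (nrow(P) < 2) return(0)
    max(stats::dist(P))
  }
  d3 <- max_pair(bphys)
  by_group_max <- function(P, g) {
    if (nrow(P) < 2) return(0)
    max(vapply(split.data.frame(as.data.frame(P), g), function(df) {
      if (nrow(df) < 2) 0 else max(stats::dist(as.matrix(df)))
    }, numeric(1)))
  }
  d2_slice <- by_group_max(bphys[, 1:2, drop = FALSE], bidx[, 3])   # in-plane, per slice
  d2_col <- by_group_max(bphys[, c(1, 3), drop = FALSE], bidx[, 2]) # row-slice plane
  d2_row <- by_group_max(bphys[, c(2, 3), drop = FALSE], bidx[, 1]) # column-slice plane

  if (nrow(phys) > 1) {
    ev <- sort(eigen(stats::cov(phys), symmetric = TRUE, only.values = TRUE)$values,
               decreasing = TRUE)
    ev[ev < 0] <- 0
  } else ev <- c(0, 0, 0)
  major <- 4 * sqrt(ev[1]); minor <- 4 * sqrt(ev[2]); least <- 4 * sqrt(ev[3])
  elong <- if (ev[1] > 0) sqrt(ev[2] / ev[1]) else NA_real_
  flat <- if (ev[1] > 0) sqrt(ev[3] / ev[1]) else NA_real_

  c(MeshVolume = mesh_vol, VoxelVolume = vox_vol_total, SurfaceArea = sa,
    SurfaceVolumeRatio = sa / mesh_vol, Sphericity = sphericity,
    Maximum3DDiameter = d3, Maximum2DDiameterSlice = d2_slice,
    Maximum2DDiameterColumn = d2_col, Maximum2DDiameterRow = d2_row,
    MajorAxisLength = major, MinorAxisLength = minor, LeastAxisLength = least,
    Elongation = elong, Flatness = flat)
}
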