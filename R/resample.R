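# Grid resampling and rigid in-plane transforms.
#
# Physical coordinates place voxel centres at (i - 0.5) * spacing along each
# axis, so resampling between spacings keeps the field of view fixed.

bilinear_sample <- function(slice, ri, ci, fill = 0) {
  H <- nrow(slice); W <- ncol(slice)
  r0 <- floor(ri); c0 <- floor(ci)
  fr <- ri - r0; fc <- ci - c0
  inside <- ri >= 1 & ri <= H & ci >= 1 & ci <= W
  r0c <- pmin(pmax(r0, 1L), H); r1c <- pmin(r0c + 1, H)
  c0c <- pmin(pmax(c0, 1L), W); c1c <- pmin(c0c + 1, W)
  v00 <- slice[cbind(r0c, c0c)]; v01 <- slice[cbind(r0c, c1c)]
  v10 <- slice[cbind(r1c, c0c)]; v11 <- slice[cbind(r1c, c1c)]
  out <- (1 - fr) * ((1 - fc) * v00 + fc * v01) + fr * ((1 - fc) * v10 + fc * v11)
  out[!inside] <- fill
  out
}

nearest_sample <- function(slice, ri, ci, fill = 0) {
  H <- nrow(slice); W <- ncol(slice)
  r <- round(ri); c <- round(ci)
  inside <- r >= 1 & r <= H & c >= 1 & c <= W
  r <- pmin(pmax(r, 1L), H); c <- pmin(pmax(c, 1L), W)
  out <- slice[cbind(r, c)]
  out[!inside] <- fill
  out
}

#' Apply a rigid in-plane transform (shift + rotation) to a volume
#'
#' Each slice is shifted by `shift_mm` (mm, row/column directions) and rotated
#' by `angle_deg` about the slice centre, then resampled on the original grid.
#' Emulates subject repositioning between repeated acquisitions.
#'
#' @param vol 3-D array with spacing attribute.
#' @param shift_mm numeric length-2 in-plane translation (mm).
#' @param angle_deg rotation angle (degrees).
#' @param method `"linear"` for intensities, `"nearest"` for masks.
#' @param fill value used outside the original field of view.
#' @return transformed volume on the same grid.
#' @export
rigid_transform <- function(vol, shift_mm = c(0, 0), angle_deg = 0,
                            method = c("linear", "nearest"), fill = 0) {
  method <- match.arg(method)
  if (all(shift_mm == 0) && angle_deg == 0) return(vol)
  sp <- spacing_of(vol)
  H <- dim(vol)[1]; W <- dim(vol)[2]; S <- dim(vol)[3]
  cy <- (H / 2 + 0.5); cx <- (W / 2 + 0.5)           # centre in voxel index units
  th <- angle_deg * pi / 180
  grid <- expand.grid(r = seq_len(H), c = seq_len(W))
  # physical offsets from centre (mm)
  yr <- (grid$r - cy) * sp[1]
  xc <- (grid$c - cx) * sp[2]
  # inverse map: undo shift, then rotate by -theta
  yr2 <- yr - shift_mm[1]
  xc2 <- xc - shift_mm[2]
  ys <- cos(th) * yr2 + sin(th) * xc2
  xs <- -sin(th) * yr2 + cos(th) * xc2
  ri <- ys / sp[1] + cy
  ci <- xs / sp[2] + cx
  sampler <- if (method == "linear") bilinear_sample else nearest_sample
  out <- array(0, dim = dim(vol))
  for (k in seq_len(S)) {
    out[, , k] <- matrix(sampler(vol[, , k], ri, ci, fill = fill), H, W)
  }
  with_spacing(out, sp)
}

#' Resample a volume to a target voxel spacing
#'
#' Trilinear interpolation (`order = 1`) for intensity volumes or
#' nearest-neighbour (`order = 0`) for masks; the physical field of view is
#' preserved and the new grid size is `round(dim * spacing / target)`.
#'
#' @param vol 3-D array with spacing attribute.
#' @param target_spacing numeric length-3 target spacing (mm).
#' @param method `"linear"` or `"nearest"`.
#' @return resampled volume carrying `target_spacing`.
#' @export
resample_volume <- function(vol, target_spacing, method = c("linear", "nearest")) {
  method <- match.arg(method)
  sp <- spacing_of(vol)
  target_spacing <- as.numeric(target_spacing)
  stopifnot(length(target_spacing) == 3L, all(target_spacing > 0))
  d <- dim(vol)
  if (isTRUE(all.equal(sp, target_spacing))) return(with_spacing(vol, sp))
  nd <- pmax(1L, as.integer(round(d * sp / target_spacing)))
  # fractional source indices of the new voxel centres
  idx <- lapply(1:3, function(a) {
    ((seq_len(nd[a]) - 0.5) * target_spacing[a]) / sp[a] + 0.5
  })
  if (method == "nearest") idx <- lapply(idx, round)
  i <- idx[[1]]; j <- idx[[2]]; k <- idx[[3]]
  clamp <- function(x, n) pmin(pmax(x, 1), n)
  if (method == "nearest") {
    i <- clamp(i, d[1]); j <- clamp(j, d[2]); k <- clamp(k, d[3])
    out <- vol[i, j, k, drop = FALSE]
    dim(out) <- nd
    return(with_spacing(out, target_spacing))
  }
  # separable trilinear gather
  i0 <- clamp(floor(i), d[1]); i1 <- clamp(i0 + 1, d[1]); fi <- clamp(i, 1, d[1]) - i0
  j0 <- clamp(floor(j), d[2]); j1 <- clamp(j0 + 1, d[2]); fj <- clamp(j, 1, d[2]) - j0
  k0 <- clamp(floor(k), d[3]); k1 <- clamp(k0 + 1, d[3]); fk <- clamp(k, 1, d[3]) - k0
  fi <- pmin(pmax(fi, 0), 1); fj <- pmin(pmax(fj, 0), 1); fk <- pmin(pmax(fk, 0), 1)
  A <- array(0, nd)
  wi <- array(fi, nd); wj <- aperm(array(fj, nd[c(2, 1, 3)]), c(2, 1, 3))
  wk <- aperm(array(fk, nd[c(3, 1, 2)]), c(2, 3, 1))
  g <- function(ii, jj, kk) {
    out <- vol[ii, jj, kk, drop = FALSE]; dim(out) <- nd; out
  }
  A <- (1 - wi) * ((1 - wj) * ((1 - wk) * g(i0, j0, k0) + wk * g(i0, j0, k1)) +
                     wj * ((1 - wk) * g(i0, j1, k0) + wk * g(i0, j1, k1))) +
    wi * ((1 - wj) * ((1 - wk) * g(i1, j0, k0) + wk * g(i1, j0, k1)) +
            wj * ((1 - wk) * g(i1, j1, k0) + wk * g(i1, j1, k1)))
  with_spacing(A, target_spacing)
}

# Exact Euclidean distance transform (Felzenszwalb & Huttenlocher), squared
# distances, separable over axes; spacing-aware. Used for signed distances to
# a mask boundary when building synthetic probability maps.
edt_1d <- function(f, step) {
  n <- length(f)
  if (n == 1L) return(f)
  d <- numeric(n); v <- integer(n); z <- numeric(n + 1L)
  k <- 1L; v[1] <- 1L; z[1] <- -Inf; z[2] <- Inf
  for (q in 2:n) {
    repeat {
      s <- ((f[q] + (q * step)^2) - (f[v[k]] + (v[k] * step)^2)) /
        (2 * step * (q - v[k]))
      if (s <= z[k]) { k <- k - 1L } else break
    }
    k <- k + 1L; v[k] <- q; z[k] <- s; z[k + 1L] <- Inf
  }
  k <- 1L
  for (q in 1:n) {
    while (z[k + 1L] < q * step) k <- k + 1L
    d[q] <- ((q - v[k]) * step)^2 + f[v[k]]
  }
  d
}

edt_squared <- function(mask, spacing) {
  d <- dim(mask)
  big <- 4 * sum((d * spacing)^2)    # finite stand-in for +Inf seeds
  f <- array(ifelse(mask > 0, 0, big), d)
  # axis 1 (rows)
  for (k in seq_len(d[3])) for (j in seq_len(d[2])) {
    f[, j, k] <- edt_1d(f[, j, k], spacing[1])
  }
  for (k in seq_len(d[3])) for (i in seq_len(d[1])) {
    f[i, , k] <- edt_1d(f[i, , k], spacing[2])
  }
  if (d[3] > 1L) {
    for (j in seq_len(d[2])) for (i in seq_len(d[1])) {
      f[i, j, ] <- edt_1d(f[i, j, ], spacing[3])
    }
  }
  f
}

#' Signed distance to a mask boundary
#'
#' Positive inside the mask, negative outside, in mm; magnitude is the exact
#' Euclidean distance to the nearest voxel of the opposite label.
#'
#' @param mask binary 3-D array with spacing attribute.
#' @return numeric array of signed distances (mm).
#' @export
signed_distance <- function(mask) {
  sp <- spacing_of(mask)
  m <- mask > 0
  if (!any(m) || all(m)) {
    return(with_spacing(array(ifelse(any(m), Inf, -Inf), dim(mask)), sp))
  }
  d_out <- sqrt(edt_squared(m, sp))        # distance to mask, 0 inside
  d_in <- sqrt(edt_squared(!m, sp))        # distance to background, 0 outside
  with_spacing(d_in - d_out, sp)
}
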