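test_that("intensity windowing clamps and rescales to [0, 255]", {
  withr::with_seed(2, {
    img <- array(rnorm(200, 50, 20), c(10, 10, 2))
    out <- intensity_window(img)
    expect_equal(min(out), 0)
    expect_equal(max(out), 255)
    mu <- mean(img); sg <- sqrt(mean((img - mu)^2))
    expect_true(all(out[img >= mu + 4 * sg] == 255))
  })
  # looped oracle on a 5-voxel image
  x <- array(c(0, 1, 2, 3, 100), c(5, 1, 1))
  mu <- mean(x); sg <- sqrt(mean((x - mu)^2))
  lo <- mu - 0.5 * sg; hi <- mu + 4 * sg
  clamped <- vapply(as.vector(x), function(v) min(max(v, lo), hi), numeric(1))
  oracle <- (clamped - min(clamped)) / (max(clamped) - min(clamped)) * 255
  expect_equal(as.vector(intensity_window(x)), oracle)
  expect_warning(intensity_window(array(7, c(2, 2, 1))),
                 class = "radstab_degenerate_input")
})

test_that("preprocessing z-scores intensities and keeps the grid at native spacing", {
  withr::with_seed(4, {
    img <- with_spacing(array(rnorm(8 * 8 * 3, 100, 25), c(8, 8, 3)),
                        c(1.458, 1.458, 5.5))
    msk <- array(0, c(8, 8, 3)); msk[3:6, 3:6, 2] <- 1
    msk <- with_spacing(msk, c(1.458, 1.458, 5.5))
    pp <- preprocess_for_radiomics(img, msk)
    expect_identical(dim(pp$image), dim(img))
    expect_lt(abs(mean(pp$image)), 1e-9)
    expect_lt(abs(sd(as.vector(pp$image)) - 1), 1e-9)
    # discretization contract: at most n_bins distinct levels in the ROI
    disc <- radstab:::discretize_slice(pp$image[, , 2], pp$mask[, , 2] > 0, 64)
    expect_lte(length(unique(disc[!is.na(disc)])), 64)
    expect_error(preprocess_for_radiomics(img, with_spacing(array(0, dim(img)),
                                                            c(1.458, 1.458, 5.5))),
                 class = "radstab_empty_roi")
  })
})

test_that("the default roster yields exactly 105 named, finite features", {
  ch <- tiny_cohort(n_per_group = 1, n_repeats = 2, seed = 19)
  pp <- preprocess_for_radiomics(ch$image[[1]], ch$gt_mask[[1]])
  fv <- extract_features(pp$image, pp$mask)
  expect_length(fv, 105)
  expect_identical(names(fv), feature_manifest())
  expect_true(all(is.finite(fv)))
  cats <- unique(sub("_.*", "", names(fv)))
  expect_setequal(cats, c("shape", "firstorder", "glcm", "glrlm", "glszm",
                          "gldm", "ngtdm"))
  # deterministic
  expect_identical(fv, extract_features(pp$image, pp$mask))
  # intensities outside the ROI do not affect intensity statistics
  img2 <- pp$image
  img2[pp$mask == 0] <- rev(img2[pp$mask == 0])
  fv2 <- extract_features(img2, pp$mask)
  expect_equal(fv2["firstorder_Mean"], fv["firstorder_Mean"])
  expect_equal(fv2["firstorder_Median"], fv["firstorder_Median"])
})

test_that("homogeneous ROIs have zero variance and zero texture contrast", {
  img <- with_spacing(array(5, c(6, 6, 2)), c(1, 1, 1))
  msk <- array(0, c(6, 6, 2)); msk[2:5, 2:5, ] <- 1
  msk <- with_spacing(msk, c(1, 1, 1))
  fv <- extract_features(img, msk)
  expect_equal(unname(fv["firstorder_Variance"]), 0)
  expect_equal(unname(fv["glcm_Contrast"]), 0)
  expect_equal(unname(fv["ngtdm_Contrast"]), 0)
})

test_that("scan-level features are unweighted means over contributing slices", {
  img <- array(0, c(6, 6, 4))
  img[, , 2] <- 10; img[, , 3] <- 20
  img <- with_spacing(img, c(1, 1, 1))
  msk <- array(0, c(6, 6, 4)); msk[2:5, 2:5, 2:3] <- 1
  msk <- with_spacing(msk, c(1, 1, 1))
  fv <- extract_features(img, msk)
  expect_equal(unname(fv["firstorder_Mean"]), 15)
  expect_equal(unname(fv["firstorder_Energy"]), (16 * 100 + 16 * 400) / 2)
})

test_that("degenerate ROIs error or warn rather than silently zero", {
  img <- with_spacing(array(rnorm(36), c(6, 6, 1)), c(1, 1, 1))
  empty <- with_spacing(array(0, c(6, 6, 1)), c(1, 1, 1))
  expect_error(extract_features(img, empty), class = "radstab_empty_roi")
  single <- empty; single[3, 3, 1] <- 1
  expect_warning(fv <- extract_features(img, single),
                 class = "radstab_undefined_features")
  expect_true(any(is.na(fv)))
  expect_equal(unname(fv["firstorder_Variance"]), 0)
})

test_that("mesh volume scales 8-fold under isotropic 2x mask scaling", {
  sphere <- function(r, n) {
    g <- seq_len(n) - (n + 1) / 2
    m <- array(0, c(n, n, n))
    for (k in seq_len(n)) m[, , k] <- outer(g, g, function(a, b) a^2 + b^2) + g[k]^2 <= r^2
    with_spacing(m * 1, c(1, 1, 1))
  }
  f1 <- radstab:::shape_features_3d(sphere(5, 14), c(1, 1, 1))
  f2 <- radstab:::shape_features_3d(sphere(10, 26), c(1, 1, 1))
  expect_lt(abs(f2["MeshVolume"] / f1["MeshVolume"] - 8) / 8, 0.05)
  expect_lt(abs(f2["SurfaceArea"] / f1["SurfaceArea"] - 4) / 4, 0.05)
  expect_lt(abs(f2["Maximum3DDiameter"] / f1["Maximum3DDiameter"] - 2) / 2, 0.06)
  # exposed-face surface counting is scale-consistent, so sphericity is too
  expect_lt(abs(f2["Sphericity"] - f1["Sphericity"]), 0.05)
})

test_that("mesh volume is monotone over nested masks", {
  base <- array(0, c(10, 10, 3)); base[2:9, 2:9, ] <- 1
  inner <- array(0, c(10, 10, 3)); inner[4:7, 4:7, 2] <- 1
  v_outer <- radstab:::shape_features_3d(with_spacing(base, c(1, 1, 1)), c(1, 1, 1))["MeshVolume"]
  v_inner <- radstab:::shape_features_3d(with_spacing(inner, c(1, 1, 1)), c(1, 1, 1))["MeshVolume"]
  expect_lt(v_inner, v_outer)
})

test_that("the GLCM kernel matches hand and brute-force oracles", {
  disc <- matrix(c(1L, 2L, 2L, 1L), 2, 2, byrow = TRUE)
  fv <- radstab:::glcm_features(disc, 2)
  expect_equal(unname(fv["Contrast"]), 0.5)   # hand: (1 + 1 + 0 + 0) / 4

  withr::with_seed(6, {
    disc2 <- matrix(sample(1:4, 49, replace = TRUE), 7, 7)
    disc2[sample(49, 10)] <- NA
    dirs <- list(c(0L, 1L), c(-1L, 1L), c(-1L, 0L), c(-1L, -1L))
    brute <- sapply(dirs, function(dd) {
      C <- matrix(0, 4, 4)
      for (r in 1:7) for (c in 1:7) {
        r2 <- r + dd[1]; c2 <- c + dd[2]
        if (r2 >= 1 && r2 <= 7 && c2 >= 1 && c2 <= 7 &&
            !is.na(disc2[r, c]) && !is.na(disc2[r2, c2])) {
          C[disc2[r, c], disc2[r2, c2]] <- C[disc2[r, c], disc2[r2, c2]] + 1
        }
      }
      P <- (C + t(C)) / sum(C + t(C))
      contrast <- 0; ent <- 0
      for (i in 1:4) for (j in 1:4) {
        contrast <- contrast + P[i, j] * (i - j)^2
        if (P[i, j] > 0) ent <- ent - P[i, j] * log2(P[i, j])
      }
      c(contrast, ent)
    })
    fv2 <- radstab:::glcm_features(disc2, 4)
    expect_equal(unname(fv2["Contrast"]), mean(brute[1, ]), tolerance = 1e-12)
    expect_equal(unname(fv2["JointEntropy"]), mean(brute[2, ]), tolerance = 1e-12)
  })
})

test_that("run-length and zone matrices match hand-worked examples", {
  disc <- matrix(c(1L, 1L, 2L, 2L, 2L, 2L), 2, 3, byrow = TRUE)
  P <- radstab:::glrlm_matrix(disc, 2, c(0L, 1L))
  want <- matrix(0, 2, 3); want[1, 2] <- 1; want[2, 1] <- 1; want[2, 3] <- 1
  expect_equal(P, want)

  disc2 <- matrix(c(1L, 1L, 2L, 1L, 2L, 2L), 2, 3, byrow = TRUE)
  Z <- radstab:::glszm_matrix(disc2, 2)
  expect_equal(dim(Z), c(2L, 3L))
  expect_equal(Z[1, 3], 1)   # one 8-connected zone of level 1, size 3
  expect_equal(Z[2, 3], 1)   # one zone of level 2, size 3

  # dependence matrix accounts for every ROI pixel once
  withr::with_seed(9, {
    disc3 <- matrix(sample(1:3, 36, replace = TRUE), 6, 6)
    disc3[sample(36, 6)] <- NA
    D <- radstab:::gldm_matrix(disc3, 3)
    expect_equal(sum(D), sum(!is.na(disc3)))
  })
})
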