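# Slice-wise texture matrices and their features: GLCM, GLRLM, GLSZM, GLDM,
# NGTDM. `disc` is an integer matrix of gray levels 1..Ng with NA outside the
# ROI. Directional matrices (GLCM, GLRLM) use the four in-plane directions
# 0/45/90/135 degrees; features are averaged over directions.

EPS <- .Machine$double.eps

DIRS_2D <- list(c(0L, 1L), c(-1L, 1L), c(-1L, 0L), c(-1L, -1L))

# shifted copy of a matrix, NA-padded
shift_mat <- function(M, dr, dc) {
  H <- nrow(M); W <- ncol(M)
  out <- matrix(NA_integer_, H, W)
  rs <- seq_len(H); cs <- seq_len(W)
  rd <- rs + dr; cd <- cs + dc
  ok_r <- rd >= 1 & rd <= H; ok_c <- cd >= 1 & cd <= W
  out[rs[ok_r], cs[ok_c]] <- M[rd[ok_r], cd[ok_c]]
  out
}

glcm_matrix <- function(disc, Ng, dir) {
  nb <- shift_mat(disc, dir[1], dir[2])
  ok <- !is.na(disc) & !is.na(nb)
  if (!any(ok)) return(NULL)
  C <- matrix(tabulate((disc[ok] - 1L) * Ng + nb[ok], nbins = Ng * Ng), Ng, Ng,
              byrow = TRUE)
  P <- C + t(C)               # symmetric
  P / sum(P)
}

glcm_features_one <- function(P) {
  Ng <- nrow(P)
  i <- matrix(seq_len(Ng), Ng, Ng)
  j <- t(i)
  px <- rowSums(P); py <- colSums(P)
  mu_x <- sum(px * seq_len(Ng)); mu_y <- sum(py * seq_len(Ng))
  sd_x <- sqrt(sum(px * (seq_len(Ng) - mu_x)^2))
  sd_y <- sqrt(sum(py * (seq_len(Ng) - mu_y)^2))
  k_sum <- 2:(2 * Ng)
  p_sum <- vapply(k_sum, function(k) sum(P[i + j == k]), numeric(1))
  k_diff <- 0:(Ng - 1)
  p_diff <- vapply(k_diff, function(k) sum(P[abs(i - j) == k]), numeric(1))
  da <- sum(k_diff * p_diff)
  hx <- -sum(px[px > 0] * log2(px[px > 0]))
  hxy <- -sum(P[P > 0] * log2(P[P > 0]))
  pxpy <- outer(px, py)
  hxy1 <- -sum(P * log2(pxpy + EPS))
  hxy2 <- -sum(pxpy * log2(pxpy + EPS))
  imc1 <- if (hx > 0) (hxy - hxy1) / hx else 0
  imc2 <- sqrt(pmax(0, 1 - exp(-2 * (hxy2 - hxy))))
  corr <- if (sd_x > 0 && sd_y > 0) {
    (sum(P * i * j) - mu_x * mu_y) / (sd_x * sd_y)
  } else 1
  offdiag <- i != j
  c(
    Autocorrelation = sum(P * i * j),
    JointAverage = mu_x,
    ClusterProminence = sum(P * (i + j - mu_x - mu_y)^4),
    ClusterShade = sum(P * (i + j - mu_x - mu_y)^3),
    ClusterTendency = sum(P * (i + j - mu_x - mu_y)^2),
    Contrast = sum(P * (i - j)^2),
    Correlation = corr,
    DifferenceAverage = da,
    DifferenceEntropy = -sum(p_diff[p_diff > 0] * log2(p_diff[p_diff > 0])),
    DifferenceVariance = sum((k_diff - da)^2 * p_diff),
    JointEnergy = sum(P^2),
    JointEntropy = hxy,
    Imc1 = imc1,
    Imc2 = imc2,
    Idm = sum(P / (1 + (i - j)^2)),
    Idmn = sum(P / (1 + ((i - j) / Ng)^2)),
    Id = sum(P / (1 + abs(i - j))),
    Idn = sum(P / (1 + abs(i - j) / Ng)),
    InverseVariance = sum(P[offdiag] / (i[offdiag] - j[offdiag])^2),
    MaximumProbability = max(P),
    SumEntropy = -sum(p_sum[p_sum > 0] * log2(p_sum[p_sum > 0])),
    SumSquares = sum(P * (i - mu_x)^2)
  )
}

glcm_features <- function(disc, Ng) {
  mats <- Filter(Negate(is.null), lapply(DIRS_2D, function(d) glcm_matrix(disc, Ng, d)))
  if (!length(mats)) return(setNames(rep(NA_real_, length(GLCM_NAMES)), GLCM_NAMES))
  rowMeans(vapply(mats, glcm_features_one, numeric(length(GLCM_NAMES))))
}

# --- GLRLM ------------------------------------------------------------------

glrlm_lines <- function(disc, dir) {
  H <- nrow(disc); W <- ncol(disc)
  if (identical(dir, c(0L, 1L))) {
    lapply(seq_len(H), function(r) disc[r, ])
  } else if (identical(dir, c(-1L, 0L))) {
    lapply(seq_len(W), function(c) disc[, c])
  } else if (identical(dir, c(-1L, 1L))) {
    # anti-diagonals: r + c constant, traversed consistently
    split(as.vector(disc), row(disc) + col(disc))
  } else {
    split(as.vector(disc), row(disc) - col(disc))
  }
}

glrlm_matrix <- function(disc, Ng, dir) {
  Lmax <- max(dim(disc))
  P <- matrix(0, Ng, Lmax)
  for (line in glrlm_lines(disc, dir)) {
    r <- rle(ifelse(is.na(line), -1L, line))
    keep <- r$values > 0
    if (any(keep)) {
      gl <- r$values[keep]; ln <- pmin(r$lengths[keep], Lmax)
      for (q in seq_along(gl)) P[gl[q], ln[q]] <- P[gl[q], ln[q]] + 1
    }
  }
  P
}

rl_features_core <- function(P, Np) {
  Nr <- sum(P)
  Ng <- nrow(P); L <- ncol(P)
  g <- seq_len(Ng); l <- seq_len(L)
  Pg <- rowSums(P); Pl <- colSums(P)
  p <- P / Nr
  gM <- matrix(g, Ng, L); lM <- matrix(l, Ng, L, byrow = TRUE)
  pnz <- p[p > 0]
  vals <- c(
    sum(P / lM^2) / Nr,
    sum(P * lM^2) / Nr,
    sum(Pg^2) / Nr,
    sum(Pg^2) / Nr^2,
    sum(Pl^2) / Nr,
    sum(Pl^2) / Nr^2,
    Nr / Np,
    sum(p * (gM - sum(p * gM))^2),
    sum(p * (lM - sum(p * lM))^2),
    -sum(pnz * log2(pnz)),
    sum(P / gM^2) / Nr,
    sum(P * gM^2) / Nr,
    sum(P / (gM^2 * lM^2)) / Nr,
    sum(P * gM^2 / lM^2) / Nr,
    sum(P * lM^2 / gM^2) / Nr,
    sum(P * gM^2 * lM^2) / Nr
  )
  vals
}

glrlm_features <- function(disc, Ng) {
  Np <- sum(!is.na(disc))
  per_dir <- vapply(DIRS_2D, function(d) {
    P <- glrlm_matrix(disc, Ng, d)
    rl_features_core(P, Np)
  }, numeric(16))
  setNames(rowMeans(per_dir), GLRLM_NAMES)
}

# --- GLSZM ------------------------------------------------------------------

# 8-connected components of equal gray level inside the ROI (union-find)
glszm_zones <- function(disc) {
  idx <- which(!is.na(disc))
  if (!length(idx)) return(NULL)
  H <- nrow(disc)
  pos <- integer(length(disc)); pos[idx] <- seq_along(idx)
  parent <- seq_along(idx)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  union <- function(a, b) {
    ra <- find(a); rb <- find(b)
    if (ra != rb) parent[ra] <<- rb
  }
  rr <- ((idx - 1L) %% H) + 1L
  cc <- ((idx - 1L) %/% H) + 1L
  g <- disc[idx]
  W <- ncol(disc)
  offs <- list(c(-1L, 0L), c(0L, -1L), c(-1L, -1L), c(-1L, 1L))
  for (o in offs) {
    nr <- rr + o[1]; ncl <- cc + o[2]
    ok <- nr >= 1 & nr <= H & ncl >= 1 & ncl <= W
    nlin <- (ncl - 1L) * H + nr
    ok[ok] <- pos[nlin[ok]] > 0
    cand <- which(ok)
    cand <- cand[disc[nlin[cand]] == g[cand]]
    for (q in cand) union(q, pos[nlin[q]])
  }
  roots <- vapply(seq_along(idx), find, integer(1))
  data.frame(g = g, zone = roots)
}

glszm_matrix <- function(disc, Ng) {
  z <- glszm_zones(disc)
  if (is.null(z)) return(matrix(0, Ng, 1))
  sizes <- stats::aggregate(list(n = z$g), by = list(g = z$g, zone = z$zone), FUN = length)
  Smax <- max(sizes$n)
  P <- matrix(0, Ng, Smax)
  for (q in seq_len(nrow(sizes))) {
    P[sizes$g[q], sizes$n[q]] <- P[sizes$g[q], sizes$n[q]] + 1
  }
  P
}

glszm_features <- function(disc, Ng) {
  Np <- sum(!is.na(disc))
  P <- glszm_matrix(disc, Ng)
  setNames(rl_features_core(P, Np), GLSZM_NAMES)
}

# --- GLDM -------------------------------------------------------------------

gldm_matrix <- function(disc, Ng, alpha = 0) {
  dep <- matrix(0L, nrow(disc), ncol(disc))
  offs <- list(c(-1L, -1L), c(-1L, 0L), c(-1L, 1L), c(0L, -1L),
               c(0L, 1L), c(1L, -1L), c(1L, 0L), c(1L, 1L))
  for (o in offs) {
    nb <- shift_mat(disc, o[1], o[2])
    match_ <- !is.na(disc) & !is.na(nb) & abs(nb - disc) <= alpha
    dep <- dep + match_
  }
  ok <- !is.na(disc)
  dmax <- 9L
  P <- matrix(tabulate((disc[ok] - 1L) * dmax + dep[ok] + 1L, nbins = Ng * dmax),
              Ng, dmax, byrow = TRUE)
  P
}

gldm_features <- function(disc, Ng) {
  P <- gldm_matrix(disc, Ng)
  Nz <- sum(P)
  g <- seq_len(nrow(P)); d <- seq_len(ncol(P))
  gM <- matrix(g, nrow(P), ncol(P)); dM <- matrix(d, nrow(P), ncol(P), byrow = TRUE)
  Pg <- rowSums(P); Pd <- colSums(P)
  p <- P / Nz
  pnz <- p[p > 0]
  setNames(c(
    sum(P / dM^2) / Nz,
    sum(P * dM^2) / Nz,
    sum(Pg^2) / Nz,
    sum(Pd^2) / Nz,
    sum(Pd^2) / Nz^2,
    sum(p * (gM - sum(p * gM))^2),
    sum(p * (dM - sum(p * dM))^2),
    -sum(pnz * log2(pnz)),
    sum(P / gM^2) / Nz,
    sum(P * gM^2) / Nz,
    sum(P / (gM^2 * dM^2)) / Nz,
    sum(P * gM^2 / dM^2) / Nz,
    sum(P * dM^2 / gM^2) / Nz,
    sum(P * gM^2 * dM^2) / Nz
  ), GLDM_NAMES)
}

# --- NGTDM ------------------------------------------------------------------

ngtdm_features <- function(disc, Ng) {
  ok <- !is.na(disc)
  nb_sum <- matrix(0, nrow(disc), ncol(disc))
  nb_cnt <- matrix(0, nrow(disc), ncol(disc))
  offs <- list(c(-1L, -1L), c(-1L, 0L), c(-1L, 1L), c(0L, -1L),
               c(0L, 1L), c(1L, -1L), c(1L, 0L), c(1L, 1L))
  for (o in offs) {
    nb <- shift_mat(disc, o[1], o[2])
    has <- !is.na(nb)
    nb_sum[has] <- nb_sum[has] + nb[has]
    nb_cnt <- nb_cnt + has
  }
  use <- ok & nb_cnt > 0
  Nvp <- sum(use)
  if (Nvp == 0) return(setNames(rep(NA_real_, 5), NGTDM_NAMES))
  abar <- nb_sum[use] / nb_cnt[use]
  gv <- disc[use]
  n_i <- tabulate(gv, nbins = Ng)
  s_i <- numeric(Ng)
  agg <- tapply(abs(gv - abar), gv, sum)
  s_i[as.integer(names(agg))] <- agg
  p_i <- n_i / Nvp
  present <- which(p_i > 0)
  Ngp <- length(present)
  iv <- seq_len(Ng)
  coarse_den <- sum(p_i * s_i)
  coarseness <- if (coarse_den > 0) 1 / coarse_den else 1e6
  if (Ngp > 1) {
    pij <- outer(p_i[present], p_i[present])
    dij2 <- outer(iv[present], iv[present], function(a, b) (a - b)^2)
    contrast <- sum(pij * dij2) / (Ngp * (Ngp - 1)) * sum(s_i) / Nvp
    busy_den <- sum(abs(outer(iv[present] * p_i[present],
                              iv[present] * p_i[present], "-")))
    busyness <- if (busy_den > 0) sum(p_i * s_i) / busy_den else 0
    absdiff <- outer(iv[present], iv[present], function(a, b) abs(a - b))
    psum <- outer(p_i[present], p_i[present], "+")
    num_c <- outer(p_i[present] * s_i[present], p_i[present] * s_i[present], "+")
    complexity <- sum(absdiff * num_c / psum) / Nvp
    strength_num <- sum(psum * dij2)
    strength <- if (sum(s_i) > 0) strength_num / sum(s_i) else 0
  } else {
    contrast <- 0; busyness <- 0; complexity <- 0; strength <- 0
  }
  c(Coarseness = coarseness, Contrast = contrast, Busyness = busyness,
    Complexity = complexity, Strength = strength)
}
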