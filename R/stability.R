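# Reliability analysis: two-way ICCs, the four-class stability taxonomy,
# the confidence-threshold scan, optimal-threshold selection and paired
# Wilcoxon comparison of ICC distributions.

two_way_ms <- function(M) {
  M <- as.matrix(M)
  n <- nrow(M); k <- ncol(M)
  if (n < 3 || k < 2) abort("reliability design needs >= 3 rows and >= 2 columns",
                            class = "radstab_input_error")
  if (anyNA(M)) abort("reliability design must have no missing cells",
                      class = "radstab_input_error")
  gm <- mean(M)
  rm_ <- rowMeans(M); cm <- colMeans(M)
  ssr <- k * sum((rm_ - gm)^2)
  ssc <- n * sum((cm - gm)^2)
  sst <- sum((M - gm)^2)
  sse <- sst - ssr - ssc
  list(msr = ssr / (n - 1), msc = ssc / (k - 1),
       mse = sse / ((n - 1) * (k - 1)), n = n, k = k)
}

#' Average-measure consistency ICC (two-way mixed effects)
#'
#' `ICC(3,k) = (MS_rows - MS_error) / MS_rows`: agreement between raters up to
#' systematic offsets, for the mean of the k measurements.
#'
#' @param M matrix/data frame, targets in rows, raters/conditions in columns.
#' @return ICC value `<= 1` (may be negative); `NA` with a warning when the
#'   between-target variance is degenerate.
#' @export
icc_consistency <- function(M) {
  ms <- two_way_ms(M)
  if (ms$msr <= 0) {
    warn("zero between-row variance: consistency ICC undefined",
         class = "radstab_undefined_icc")
    return(NA_real_)
  }
  (ms$msr - ms$mse) / ms$msr
}

#' Average-measure absolute-agreement ICC (two-way random effects)
#'
#' `ICC(2,k) = (MS_rows - MS_error) / (MS_rows + (MS_cols - MS_error) / n)`:
#' systematic rater offsets count against agreement.
#'
#' @inheritParams icc_consistency
#' @return ICC value `<= 1`; `NA` with a warning on degenerate variance.
#' @export
icc_agreement <- function(M) {
  ms <- two_way_ms(M)
  den <- ms$msr + (ms$msc - ms$mse) / ms$n
  if (ms$msr <= 0 || den <= 0) {
    warn("degenerate variance decomposition: agreement ICC undefined",
         class = "radstab_undefined_icc")
    return(NA_real_)
  }
  (ms$msr - ms$mse) / den
}

#' Assign the four-class stability label
#'
#' Class 1: reproducible and repeatable (both ICCs at or above the cutoff);
#' class 2: only reproducible (segmentation); class 3: only repeatable
#' (scan-rescan); class 4: neither. Undefined (`NA`) ICCs count below the
#' cutoff.
#'
#' @param icc_s consistency ICC vs segmentation variability.
#' @param icc_a absolute-agreement ICC vs scan-rescan variability.
#' @param cutoff inclusive threshold in `(0, 1)`, default 0.8.
#' @return integer class in `1:4` (vectorized).
#' @export
classify_stability <- function(icc_s, icc_a, cutoff = 0.8) {
  stopifnot(cutoff > 0, cutoff < 1)
  s_ok <- !is.na(icc_s) & icc_s >= cutoff
  a_ok <- !is.na(icc_a) & icc_a >= cutoff
  ifelse(s_ok & a_ok, 1L, ifelse(s_ok, 2L, ifelse(a_ok, 3L, 4L)))
}

feature_cols <- function(tbl) {
  setdiff(names(tbl), c("subject_id", "group", "repeat_index", "mask_source"))
}

# rows = scans of one group, 2 columns (GT vs method features), per feature
icc_s_per_feature <- function(tbl, source, group) {
  sub <- tbl[tbl$group == group & tbl$mask_source %in% c("GT", source), ]
  fc <- feature_cols(sub)
  wide_gt <- sub[sub$mask_source == "GT", ]
  wide_m <- sub[sub$mask_source == source, ]
  key <- function(x) paste(x$subject_id, x$repeat_index)
  if (!setequal(key(wide_gt), key(wide_m)) || anyDuplicated(key(wide_gt))) {
    missing <- setdiff(key(wide_gt), key(wide_m))
    abort(paste0("incomplete design for ICC_S: missing cells ",
                 paste(missing, collapse = ", ")), class = "radstab_incomplete_design")
  }
  wide_m <- wide_m[match(key(wide_gt), key(wide_m)), ]
  vapply(fc, function(f) {
    M <- cbind(wide_gt[[f]], wide_m[[f]])
    if (anyNA(M)) return(NA_real_)          # degenerate ROI: ICC undefined
    suppressWarnings(icc_consistency(M))
  }, numeric(1))
}

# rows = subjects (groups pooled), columns = repeats, per feature
icc_a_per_feature <- function(tbl, source) {
  sub <- tbl[tbl$mask_source == source, ]
  fc <- feature_cols(sub)
  subs <- sort(unique(sub$subject_id))
  reps <- sort(unique(sub$repeat_index))
  key <- paste(sub$subject_id, sub$repeat_index)
  want <- as.vector(outer(subs, reps, paste))
  if (!setequal(key, want) || anyDuplicated(key)) {
    abort(paste0("incomplete design for ICC_A: missing cells ",
                 paste(setdiff(want, key), collapse = ", ")),
          class = "radstab_incomplete_design")
  }
  ord <- match(want, key)
  vapply(fc, function(f) {
    M <- matrix(sub[[f]][ord], nrow = length(subs), ncol = length(reps))
    if (anyNA(M)) return(NA_real_)          # degenerate ROI: ICC undefined
    suppressWarnings(icc_agreement(M))
  }, numeric(1))
}

#' Scan confidence thresholds for feature stability
#'
#' For every threshold and group, computes per-feature ICC_S (consistency,
#' scans as rows, ground truth vs confidence-mask features as the two
#' conditions) and ICC_A (absolute agreement over the repeated acquisitions,
#' subjects as rows, both groups pooled), assigns stability classes, counts
#' them, and selects the optimal threshold per group.
#'
#' @param features feature table ([cohort_feature_table()]) containing `GT`
#'   and `CL_<th>` mask sources for every scan.
#' @param thresholds confidence levels (percent) to scan.
#' @param cutoff ICC cutoff for the class taxonomy.
#' @return object of class `threshold_scan`: list with `icc` (tibble of
#'   per-feature ICCs and classes by group and threshold), `counts` (tibble of
#'   class counts), and `th_opt` (named per group).
#' @export
threshold_scan <- function(features, thresholds = seq(10, 100, by = 10), cutoff = 0.8) {
  groups <- sort(unique(features$group))
  res <- list()
  for (th in thresholds) {
    src <- sprintf("CL_%d", as.integer(th))
    if (!src %in% features$mask_source) {
      abort(sprintf("mask source %s absent from the feature table", src),
            class = "radstab_input_error")
    }
    icc_a <- icc_a_per_feature(features, src)
    for (g in groups) {
      icc_s <- icc_s_per_feature(features, src, g)
      icc_a_g <- unname(icc_a[names(icc_s)])
      res[[length(res) + 1L]] <- tibble::tibble(
        group = g, th = th, feature = names(icc_s),
        icc_s = unname(icc_s), icc_a = icc_a_g,
        class = classify_stability(unname(icc_s), icc_a_g, cutoff)
      )
    }
  }
  icc <- dplyr::bind_rows(res)
  counts <- icc |>
    dplyr::count(.data$group, .data$th, .data$class) |>
    tidyr::complete(group = groups, th = thresholds, class = 1:4,
                    fill = list(n = 0L))
  th_opt <- vapply(groups, function(g) {
    select_thopt(counts[counts$group == g, ])
  }, numeric(1))
  structure(list(icc = icc, counts = counts, th_opt = th_opt, cutoff = cutoff),
            class = "threshold_scan")
}

#' @export
print.threshold_scan <- function(x, ...) {
  cat("<threshold_scan> ", length(unique(x$icc$feature)), " features, thresholds ",
      paste(sort(unique(x$icc$th)), collapse = ", "), "\n", sep = "")
  cat("th_opt:", paste(names(x$th_opt), x$th_opt, sep = " = ", collapse = ", "), "\n")
  invisible(x)
}

#' Select the optimal confidence threshold
#'
#' The threshold minimizing the number of class-4 features; ties broken by
#' maximizing the class-1 count, remaining ties by the smallest threshold.
#'
#' @param counts tibble with columns `th`, `class`, `n` (one group).
#' @return the selected threshold.
#' @export
select_thopt <- function(counts) {
  wide <- counts |>
    dplyr::group_by(.data$th) |>
    dplyr::summarise(n1 = sum(.data$n[.data$class == 1]),
                     n4 = sum(.data$n[.data$class == 4])) |>
    dplyr::arrange(.data$th)
  cand <- wide[wide$n4 == min(wide$n4), ]
  cand <- cand[cand$n1 == max(cand$n1), ]
  min(cand$th)
}

#' Paired two-tailed Wilcoxon signed-rank test with Pratt zero handling
#'
#' Compares two paired vectors (e.g. per-feature ICC distributions of two
#' methods). Zero differences are ranked with the rest and then dropped from
#' the statistic (Pratt); the null is exact (`dsignrank`) when there are no
#' zeros and `n <= 25`, otherwise a normal approximation with continuity and
#' Pratt corrections is used. All-zero differences give a degenerate test with
#' p = 1.
#'
#' @param a,b equal-length paired numeric vectors.
#' @return list with `statistic` (V, sum of positive-difference ranks) and
#'   `p_value`.
#' @export
wilcoxon_compare <- function(a, b) {
  stopifnot(length(a) == length(b))
  d <- b - a
  d <- d[!is.na(d)]
  n_all <- length(d)
  nz <- d != 0
  if (!any(nz)) {
    return(list(statistic = 0, p_value = 1, degenerate = TRUE))
  }
  r_all <- rank(abs(d))                     # zeros included in ranking (Pratt)
  V <- sum(r_all[d > 0])
  n <- sum(nz)
  ties <- any(duplicated(abs(d[nz])))
  if (!any(!nz) && !ties && n <= 25) {
    V0 <- sum(rank(abs(d))[d > 0])
    p_le <- stats::psignrank(V0, n)
    p_ge <- stats::psignrank(V0 - 1, n, lower.tail = FALSE)
    p <- min(1, 2 * min(p_le, p_ge))
  } else {
    n0 <- sum(!nz)
    mu <- n_all * (n_all + 1) / 4 - n0 * (n0 + 1) / 4
    t_abs <- table(r_all)
    tie_corr <- sum(t_abs^3 - t_abs) / 48
    sig2 <- n_all * (n_all + 1) * (2 * n_all + 1) / 24 -
      n0 * (n0 + 1) * (2 * n0 + 1) / 24 - tie_corr
    z <- (V - mu - sign(V - mu) * 0.5) / sqrt(sig2)
    p <- min(1, 2 * pnorm(-abs(z)))
  }
  list(statistic = V, p_value = p, degenerate = FALSE)
}
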