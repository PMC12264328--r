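test_that("ICC forms match the two-way ANOVA oracle on random tables", {
  withr::with_seed(12, {
    for (i in 1:50) {
      n <- sample(5:12, 1); k <- sample(2:6, 1)
      M <- matrix(rnorm(n * k, 10, 2), n, k) + rnorm(n, 0, 2)
      oracle <- aov_icc(M)
      expect_lt(abs(icc_consistency(M) - oracle$consistency), 1e-10)
      expect_lt(abs(icc_agreement(M) - oracle$agreement), 1e-10)
    }
  })
})

test_that("identical columns give perfect reliability", {
  x <- rnorm(8, 5, 2)
  M <- cbind(x, x, x)
  expect_equal(icc_consistency(M), 1)
  expect_equal(icc_agreement(M), 1)
})

test_that("constant rater offsets spare consistency but penalize agreement", {
  withr::with_seed(31, {
    x <- rnorm(10, 0, 3)
    M <- cbind(x, x + 2, x + 5)
    expect_equal(icc_consistency(M), 1)
    expect_lt(icc_agreement(M), 1)
    expect_lt(icc_agreement(M), icc_consistency(M))
    # hand evaluation on a 4 x 2 table with a pure offset
    H <- cbind(c(1, 2, 3, 4), c(2, 3, 4, 5))
    n <- 4; k <- 2
    msr <- var(rowMeans(H)) * k
    msc <- sum((colMeans(H) - mean(H))^2) * n / (k - 1)
    mse <- 0
    expect_equal(icc_agreement(H), (msr - mse) / (msr + (msc - mse) / n))
    expect_equal(icc_consistency(H), 1)
  })
})

test_that("degenerate reliability designs are rejected or flagged", {
  expect_error(icc_consistency(matrix(1:4, 2, 2)), class = "radstab_input_error")
  expect_warning(v <- icc_consistency(matrix(5, 4, 3)), class = "radstab_undefined_icc")
  expect_true(is.na(v))
})

test_that("ICC_A recovers the theoretical average-measure reliability", {
  withr::with_seed(99, {
    n <- 200; k <- 5; sb <- 1; sw <- 1
    M <- matrix(rnorm(n, 0, sb), n, k) + matrix(rnorm(n * k, 0, sw), n, k)
    rho_k <- sb^2 / (sb^2 + sw^2 / k)       # Spearman-Brown, average measure
    expect_lt(abs(icc_agreement(M) - rho_k), 0.05)
  })
})

test_that("stability classes follow the taxonomy with an inclusive boundary", {
  expect_identical(classify_stability(0.9, 0.9), 1L)
  expect_identical(classify_stability(0.9, 0.5), 2L)
  expect_identical(classify_stability(0.5, 0.9), 3L)
  expect_identical(classify_stability(0.5, 0.5), 4L)
  expect_identical(classify_stability(0.8, 0.8), 1L)
  expect_identical(classify_stability(NA_real_, NA_real_), 4L)
  expect_identical(classify_stability(NA_real_, 0.9), 3L)
})

test_that("the optimal threshold minimizes class 4 then maximizes class 1", {
  toy <- function(tab) {
    tibble::tibble(
      th = rep(as.numeric(names(tab)), each = 4),
      class = rep(1:4, length(tab)),
      n = unlist(tab, use.names = FALSE)
    )
  }
  # min n4 tie between 80 and 90; larger n1 picks 90
  t1 <- toy(list(`60` = c(5, 0, 0, 10), `80` = c(6, 0, 1, 8), `90` = c(7, 0, 0, 8)))
  expect_equal(select_thopt(t1), 90)
  # unique minimizer
  t2 <- toy(list(`50` = c(1, 0, 0, 9), `70` = c(1, 0, 5, 4), `90` = c(1, 0, 0, 9)))
  expect_equal(select_thopt(t2), 70)
  # full tie falls back to the smallest threshold
  t3 <- toy(list(`10` = c(2, 2, 2, 2), `20` = c(2, 2, 2, 2)))
  expect_equal(select_thopt(t3), 10)
})

test_that("threshold scan partitions features and is perfect on perfect data", {
  tbl <- synthetic_feature_table(n_subjects = 6, n_repeats = 3,
                                 sources = c("GT", "MP", "CL_40", "CL_80"),
                                 f = c("fA", "fB", "fC"), noise = 0)
  sc <- threshold_scan(tbl, thresholds = c(40, 80))
  expect_true(all(sc$icc$class == 1L))
  sums <- dplyr::count(sc$counts, .data$group, .data$th, wt = .data$n)
  expect_true(all(sums$n == 3))
  expect_s3_class(tidy(sc), "tbl_df")
  expect_true(all(glance(sc)$n1 == 3))

  noisy <- synthetic_feature_table(n_subjects = 6, n_repeats = 3,
                                   sources = c("GT", "MP", "CL_40", "CL_80"),
                                   f = c("fA", "fB", "fC"), noise = 2, seed = 5)
  sc2 <- threshold_scan(noisy, thresholds = c(40, 80))
  sums2 <- dplyr::count(sc2$counts, .data$group, .data$th, wt = .data$n)
  expect_true(all(sums2$n == 3))
  expect_true(all(sc2$th_opt %in% c(40, 80)))
})

test_that("incomplete designs are reported with the offending cells", {
  tbl <- synthetic_feature_table(sources = c("GT", "CL_50"))
  broken <- tbl[-which(tbl$mask_source == "CL_50")[1], ]
  expect_error(threshold_scan(broken, thresholds = 50),
               class = "radstab_incomplete_design")
  expect_error(threshold_scan(tbl, thresholds = 60), class = "radstab_input_error")
})

test_that("the signed-rank comparison handles shifts, zeros and small n exactly", {
  expect_equal(wilcoxon_compare(rep(1, 5), rep(1, 5))$p_value, 1)
  withr::with_seed(17, {
    a <- rnorm(20)
    res <- wilcoxon_compare(a, a + 0.1)
    expect_lt(res$p_value, 0.05)
    expect_equal(res$statistic, sum(rank(abs(0.1 + 0 * a))[rep(TRUE, 20)]))
    # statistic equals the brute-force rank sum for n <= 10
    for (i in 1:5) {
      x <- rnorm(8); y <- rnorm(8)
      d <- y - x
      V_brute <- sum(rank(abs(d))[d > 0])
      expect_equal(wilcoxon_compare(x, y)$statistic, V_brute)
      # zero-free case agrees with the base-R exact test
      p_ref <- stats::wilcox.test(y, x, paired = TRUE, exact = TRUE)$p.value
      expect_equal(wilcoxon_compare(x, y)$p_value, p_ref)
    }
  })
})
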