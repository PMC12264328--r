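make_discrim_table <- function(n_subjects = 20, seed = 1, informative = TRUE,
                               duplicate = FALSE) {
  withr::with_seed(seed, {
    y <- rep(c("CKD", "HC"), each = n_subjects / 2)
    tbl <- tibble::tibble(
      subject_id = sprintf("P%02d", seq_len(n_subjects)),
      group = y, repeat_index = 1L, mask_source = "CL_50",
      shape_MeshVolume = rnorm(n_subjects, 100, 10)
    )
    tbl$sig <- if (informative) (y == "CKD") * 3 + rnorm(n_subjects, 0, 0.5)
               else rnorm(n_subjects)
    for (i in 1:6) tbl[[paste0("noise", i)]] <- rnorm(n_subjects)
    if (duplicate) tbl$sig_dup <- tbl$sig + rnorm(n_subjects, 0, 1e-3)
    tbl
  })
}

test_that("feature filtering drops zero-variance and volume-correlated columns", {
  tbl <- make_discrim_table()
  tbl$constant <- 5
  tbl$vol2 <- 2 * tbl$shape_MeshVolume
  withr::with_seed(3, {
    # controlled correlation just under the cutoff
    v <- as.vector(scale(tbl$shape_MeshVolume))
    e <- as.vector(scale(resid(lm(rnorm(nrow(tbl)) ~ v))))
    r <- 0.79
    tbl$near <- r * v + sqrt(1 - r^2) * e
  })
  out <- filter_features(tbl)
  expect_false("constant" %in% names(out))
  expect_false("vol2" %in% names(out))
  expect_true("near" %in% names(out))
  expect_true("shape_MeshVolume" %in% names(out))
  expect_equal(abs(cor(tbl$near, tbl$shape_MeshVolume)), 0.79, tolerance = 1e-12)
  expect_error(filter_features(dplyr::select(tbl, -"shape_MeshVolume")),
               class = "radstab_config_error")
})

test_that("bootstrapped mRMR finds the informative feature and penalizes duplicates", {
  tbl <- make_discrim_table(n_subjects = 100, seed = 7)
  sel <- mrmr_bootstrap(tbl, tbl$group, n_boot = 50, k = 5, seed = 2)
  expect_equal(unname(sel$frequency$frequency[sel$frequency$feature == "sig"]), 1)
  expect_true("sig" %in% sel$selected)
  expect_identical(sel$selected,
                   mrmr_bootstrap(tbl, tbl$group, n_boot = 50, k = 5, seed = 2)$selected)

  dup <- make_discrim_table(n_subjects = 100, seed = 7, duplicate = TRUE)
  sel2 <- mrmr_bootstrap(dup, dup$group, n_boot = 50, k = 5, seed = 2)
  expect_lt(sum(c("sig", "sig_dup") %in% sel2$selected), 2)
  expect_error(mrmr_bootstrap(tbl[, 1:6], tbl$group, k = 5),
               class = "radstab_selection_error")
})

test_that("leave-one-patient-out classification separates separable data", {
  tbl <- make_discrim_table(n_subjects = 16, seed = 11)
  rep_ <- fit_eval_lopo(tbl, c("sig", "noise1"))
  expect_equal(rep_$auc, 1)
  expect_equal(sum(!is.na(rep_$predictions$prob)), nrow(tbl))
  expect_true(all(rep_$predictions$prob >= 0 & rep_$predictions$prob <= 1))
  expect_s3_class(tidy(rep_), "tbl_df")
  expect_equal(glance(rep_)$auc, 1)
})

test_that("the permutation null gives chance-level AUC", {
  tbl <- make_discrim_table(n_subjects = 50, seed = 13, informative = FALSE)
  withr::with_seed(21, {
    aucs <- replicate(100, {
      t2 <- tbl
      t2$group <- sample(t2$group)
      fit_eval_lopo(t2, c("sig", "noise1", "noise2", "noise3", "noise4"))$auc
    })
  })
  expect_gt(mean(aucs), 0.4)
  expect_lt(mean(aucs), 0.6)
})

test_that("AUC equals exhaustive pair counting and pROC agrees", {
  skip_if_not_installed("pROC")
  withr::with_seed(5, {
    n <- 24
    y <- rep(c(0, 1), each = n / 2)
    s <- rnorm(n) + y
    brute <- 0
    for (i in which(y == 1)) for (j in which(y == 0)) {
      brute <- brute + (s[i] > s[j]) + 0.5 * (s[i] == s[j])
    }
    brute <- brute / (sum(y == 1) * sum(y == 0))
    expect_equal(auc_mann_whitney(s, y), brute)
    expect_equal(auc_mann_whitney(s, y),
                 as.numeric(suppressMessages(pROC::auc(y, s))))
  })
})

test_that("the DeLong test matches pROC and is exact for identical classifiers", {
  withr::with_seed(8, {
    n <- 40
    y <- rep(c(0, 1), each = n / 2)
    a <- rnorm(n) + y
    b <- 0.7 * a + 0.5 * rnorm(n)
    expect_equal(delong_test(a, a, y)$p_value, 1)
    res <- delong_test(a, b, y)
    skip_if_not_installed("pROC")
    ref <- suppressMessages(pROC::roc.test(pROC::roc(y, a), pROC::roc(y, b),
                                           method = "delong"))
    expect_equal(res$p_value, as.numeric(ref$p.value), tolerance = 1e-9)
    expect_equal(res$auc_a - res$auc_b,
                 as.numeric(ref$estimate[1] - ref$estimate[2]), tolerance = 1e-12)
  })
  expect_error(delong_test(1:4 / 4, 1:4 / 4, rep(1, 4)), class = "radstab_input_error")
})

test_that("the DeLong test holds its nominal type-I error", {
  withr::with_seed(42, {
    n <- 60
    y <- rep(c(0, 1), each = n / 2)
    rejections <- mean(replicate(1000, {
      a <- rnorm(n) + y
      b <- rnorm(n) + y      # independent score, same true AUC
      delong_test(a, b, y)$p_value < 0.05
    }))
  })
  expect_gte(rejections, 0.03)
  expect_lte(rejections, 0.07)
})
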