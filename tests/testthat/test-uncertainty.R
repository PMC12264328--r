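test_that("mean prediction is the voxelwise replicate average", {
  st <- structure(array(c(0.2, 0.8), c(1, 1, 1, 2)), spacing = c(1, 1, 1))
  mp <- mean_prediction(st)
  expect_equal(as.numeric(mp$pbar), 0.5)
  expect_equal(as.numeric(mp$mp_mask), 1)   # tie maps to foreground

  cst <- structure(array(0.3, c(2, 2, 2, 5)), spacing = c(1, 1, 1))
  expect_true(all(mean_prediction(cst)$pbar == 0.3))

  st2 <- random_stack(c(10, 8, 8), T_rep = 7, seed = 3)
  looped <- apply(st2, c(1, 2, 3), mean)
  expect_lt(max(abs(mean_prediction(st2)$pbar - looped)), 1e-12)
})

test_that("uncertainty decomposition matches its closed forms", {
  mk <- function(vals) structure(array(rep(vals, each = 1), c(1, 1, 1, length(vals))),
                                 spacing = c(1, 1, 1))
  u1 <- uncertainty_decompose(mk(rep(1, 4)))
  expect_equal(as.numeric(c(u1$aleatoric, u1$epistemic, u1$predictive)), c(0, 0, 0))

  u2 <- uncertainty_decompose(mk(rep(0.5, 4)))
  expect_equal(as.numeric(c(u2$aleatoric, u2$epistemic, u2$predictive)), c(0.25, 0, 0.25))

  u3 <- uncertainty_decompose(mk(c(0, 0, 1, 1)))
  expect_equal(as.numeric(c(u3$aleatoric, u3$epistemic, u3$predictive)), c(0, 0.25, 0.25))
})

test_that("predictive uncertainty equals pbar(1-pbar) and is bounded", {
  for (s in 1:5) {
    st <- random_stack(c(6, 6, 3), T_rep = 9, seed = s)
    u <- uncertainty_decompose(st)
    pbar <- mean_prediction(st)$pbar
    expect_lt(max(abs(u$predictive - pbar * (1 - pbar))), 1e-12)
    expect_lt(max(abs(u$predictive - (u$aleatoric + u$epistemic))), 1e-15)
    expect_true(all(u$aleatoric >= 0) && all(u$epistemic >= 0))
    expect_true(max(u$predictive) <= 0.25 + 1e-15)
  }
})

test_that("confidence masks follow the vote rule and nest", {
  # one voxel foreground in 5 of 50 replicates: in CL_10, not CL_20
  v <- c(rep(0.9, 5), rep(0.1, 45))
  st <- structure(array(v, c(1, 1, 1, 50)), spacing = c(1, 1, 1))
  cm <- confidence_masks(st)
  expect_equal(as.numeric(cm$masks$CL_10), 1)
  expect_equal(as.numeric(cm$masks$CL_20), 0)

  st_all <- structure(array(0.8, c(1, 1, 1, 50)), spacing = c(1, 1, 1))
  expect_equal(as.numeric(confidence_masks(st_all)$masks$CL_100), 1)

  st3 <- random_stack(c(8, 8, 2), T_rep = 20, seed = 11)
  cm3 <- confidence_masks(st3)
  ths <- seq(10, 100, by = 10)
  for (i in seq_len(length(ths) - 1)) {
    hi <- cm3$masks[[sprintf("CL_%d", ths[i + 1])]]
    lo <- cm3$masks[[sprintf("CL_%d", ths[i])]]
    expect_true(all(hi <= lo))
  }
  # just above 50% the mask is the majority vote of classified replicates
  maj <- (apply(st3 >= 0.5, c(1, 2, 3), mean) > 0.5) * 1
  cl51 <- confidence_masks(st3, thresholds = 51)$masks$CL_51
  expect_equal(as.numeric(cl51), as.numeric(maj))
  expect_error(confidence_masks(st3, thresholds = 0), class = "radstab_parameter_error")
  expect_error(confidence_masks(st3, thresholds = 101), class = "radstab_parameter_error")
})

test_that("dice score counts overlap and handles degenerate masks", {
  a <- array(0, c(4, 4, 1)); b <- array(0, c(4, 4, 1))
  a[1:2, 1, 1] <- 1; b[1:2, 1, 1] <- 1
  expect_equal(dice_score(a, b), 1)
  b2 <- array(0, c(4, 4, 1)); b2[3:4, 4, 1] <- 1
  expect_equal(dice_score(a, b2), 0)
  b3 <- array(0, c(4, 4, 1)); b3[2:3, 1, 1] <- 1   # |A|=2,|B|=2,|A int B|=1
  expect_equal(dice_score(a, b3), 0.5)
  expect_equal(dice_score(array(0, c(2, 2, 1)), array(0, c(2, 2, 1))), 1)
  expect_error(dice_score(a, array(0, c(3, 3, 1))), class = "radstab_input_error")
  expect_true(dice_score(a, b) == dice_score(b, a))
})

test_that("dice losses reproduce hand-computed values", {
  eps <- 1e-6
  y <- array(c(1, 0), c(2, 1, 1)); p <- array(c(0.5, 0.5), c(2, 1, 1))
  expect_equal(dice_loss(p, y), 1 - (2 * 0.5 + eps) / (1 + 1 + eps))
  expect_equal(dice_plus_loss(p, y, gamma = 2),
               1 - (1 + eps) / (1 + 0.25 + 0.25 + eps))
  yb <- array(c(1, 0, 1, 0), c(2, 2, 1))
  expect_lt(dice_loss(yb, yb), 1e-6)
  expect_lt(dice_plus_loss(yb, yb, gamma = 3), 1e-6)
  z <- array(0, c(2, 2, 1))
  expect_equal(dice_loss(z, z), 0)
  expect_error(dice_plus_loss(p, y, gamma = 0), class = "radstab_parameter_error")
  expect_error(dice_loss(array(2, c(1, 1, 1)), array(1, c(1, 1, 1))),
               class = "radstab_input_error")
})

test_that("the focal Dice loss at gamma = 1 collapses to the plain Dice loss", {
  withr::with_seed(8, {
    for (i in 1:100) {
      d <- c(sample(2:5, 1), sample(2:5, 1), sample(1:3, 1))
      p <- array(runif(prod(d)), d)
      y <- array(rbinom(prod(d), 1, 0.5), d)
      expect_lt(abs(dice_plus_loss(p, y, gamma = 1) - dice_loss(p, y)), 1e-12)
    }
  })
})

test_that("histogram KL kernel matches the closed form and its null", {
  # P = (.5,.5) vs Q = (.25,.75) without smoothing: 0.5 ln2 + 0.5 ln(2/3)
  p <- c(0.5, 0.5); q <- c(0.25, 0.75)
  expect_equal(sum(p * log(p / q)), 0.5 * log(2) + 0.5 * log(2 / 3))
  # the smoothed kernel on large counts approaches it
  expect_lt(abs(radstab:::kl_from_counts(c(5e5, 5e5), c(25e4, 75e4)) -
                  0.1438), 0.001)
  expect_equal(radstab:::kl_from_counts(c(10, 20, 30), c(10, 20, 30)), 0)
})

test_that("KL separability vanishes under the null and flags degenerate input", {
  withr::with_seed(3, {
    n <- 1e5
    u <- c(rbeta(n, 2, 5), rbeta(n, 2, 5))
    pred <- array(c(rep(1, n), rep(1, n)), c(2 * n, 1, 1))
    gt <- array(c(rep(1, n), rep(0, n)), c(2 * n, 1, 1))
    kl <- kl_uncertainty_separability(array(u, c(2 * n, 1, 1)), pred, gt)
    expect_lt(kl, 0.05)
  })
  ok <- array(1, c(2, 2, 1))
  expect_error(kl_uncertainty_separability(array(0.1, c(2, 2, 1)), ok, ok),
               class = "radstab_undefined_divergence")
})
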