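test_that("empirical AUROC matches hand-computed cases", {
  expect_equal(empirical_auc(c(1, 2, 3, 4), c(0, 0, 1, 1)), 1.0)
  expect_equal(empirical_auc(rep(2, 6), c(0, 1, 0, 1, 0, 1)), 0.5)
  expect_equal(empirical_auc(c(1, 2, 2, 3), c(0, 0, 1, 1)), 0.875)
  expect_error(empirical_auc(1:4, c(1, 1, 1, 1)), "both classes")
})

test_that("empirical AUROC equals brute-force concordance on random data", {
  set.seed(42)
  for (i in 1:25) {
    n <- sample(5:30, 1)
    scores <- sample(round(rnorm(n), 1))          # rounding induces ties
    labels <- c(0, 1, rbinom(n - 2, 1, 0.5))
    expect_equal(empirical_auc(scores, labels),
                 brute_force_auc(scores, labels))
    # tie-aware complement identity
    expect_equal(empirical_auc(scores, labels) +
                   empirical_auc(-scores, labels), 1.0)
  }
})

test_that("perfect separation collapses the DeLong CI and is flagged", {
  r <- delong_ci(c(1, 2, 3, 10, 11, 12), c(0, 0, 0, 1, 1, 1))
  expect_equal(r$auc, 1)
  expect_true(r$degenerate)
  expect_equal(r$ci_low, 1)
  expect_equal(r$ci_high, 1)
})

test_that("DeLong agrees with pROC and with a bootstrap oracle", {
  skip_if_not_installed("pROC")
  set.seed(9)
  scores <- rnorm(80)
  labels <- rbinom(80, 1, 0.35)
  scores[labels == 1] <- scores[labels == 1] + 1
  mine <- delong_ci(scores, labels)
  ref <- as.numeric(pROC::ci.auc(pROC::roc(labels, scores, quiet = TRUE),
                                 method = "delong"))
  expect_equal(c(mine$ci_low, mine$auc, mine$ci_high), ref,
               tolerance = 1e-10)
  bse <- bootstrap_auc_se(scores, labels, n_boot = 2000, seed = 4)
  expect_lt(abs(mine$se - bse) / bse, 0.15)
})

test_that("DeLong intervals achieve near-nominal coverage under the null", {
  set.seed(77)
  covered <- vapply(1:200, function(i) {
    scores <- rnorm(40)
    labels <- rep(c(0, 1), 20)
    r <- delong_ci(scores, labels)
    r$ci_low <= 0.5 && 0.5 <= r$ci_high
  }, logical(1))
  expect_gte(mean(covered), 0.93)
})

test_that("comparing a classifier with itself gives z = 0, p = 1", {
  s <- c(0.2, 0.8, 0.4, 0.9, 0.1, 0.7)
  l <- c(0, 1, 0, 1, 0, 1)
  out <- delong_compare(s, s, l)
  expect_equal(out$z, 0)
  expect_equal(out$p_value, 1)
  expect_error(delong_compare(s, s[-1], l), "equal length")
})

test_that("the paired DeLong statistic matches direct formula evaluation", {
  # 6 subjects, hand-evaluated placement covariance
  labels <- c(1, 1, 1, 0, 0, 0)
  a <- c(10, 9, 8, 3, 2, 1)         # perfectly separating
  b <- c(5, 2, 6, 4, 9, 1)          # mixed
  out <- delong_compare(a, b, labels)
  psi_b <- outer(b[1:3], b[4:6], ">") + 0.5 * outer(b[1:3], b[4:6], "==")
  auc_b <- mean(psi_b)
  d10 <- 1 - rowMeans(psi_b)
  d01 <- 1 - colMeans(psi_b)
  v <- var(d10) / 3 + var(d01) / 3
  expect_equal(out$z, (1 - auc_b) / sqrt(v), tolerance = 1e-12)
})

test_that("the paired DeLong test holds its type-I error", {
  set.seed(101)
  rejections <- vapply(1:200, function(i) {
    labels <- rep(c(0, 1), 50)
    delong_compare(rnorm(100), rnorm(100), labels)$p_value < 0.05
  }, logical(1))
  expect_gte(mean(rejections), 0.02)
  expect_lte(mean(rejections), 0.09)
})

test_that("operating-point performance at a cutoff is counted exactly", {
  out <- confusion_at_cutoff(c(1.0, 1.1, 1.3, 1.5), c(0, 0, 1, 1), 1.2)
  expect_equal(out$sensitivity, 1)
  expect_equal(out$specificity, 1)
  expect_equal(out$tp + out$fp + out$tn + out$fn, 4)

  # 11 of 13 positives above the cutoff: the printed 85% sensitivity
  scores <- c(seq(1.3, 1.9, length.out = 11), 1.0, 1.1,
              seq(0.5, 1.15, length.out = 20))
  labels <- rep(c(1, 0), c(13, 20))
  out2 <- confusion_at_cutoff(scores, labels, 1.2)
  expect_equal(out2$sensitivity, 11 / 13)
  expect_equal(round(100 * out2$sensitivity), 85)

  # cutoff above every score
  out3 <- confusion_at_cutoff(c(0.5, 0.9, 1.4), c(0, 0, 1), 2)
  expect_equal(out3$sensitivity, 0)
  expect_equal(out3$specificity, 1)

  # boundary scores are negative under the strict convention
  out4 <- confusion_at_cutoff(c(1.2, 1.2), c(1, 0), 1.2)
  expect_equal(out4$sensitivity, 0)
  expect_equal(out4$specificity, 1)

  # Wilson intervals stay inside [0, 1]
  expect_true(all(c(out2$sens_low, out2$spec_low) >= 0))
  expect_true(all(c(out2$sens_high, out2$spec_high) <= 1))
})

test_that("the Youden-optimal cutoff behaves on canonical cases", {
  j <- youden_optimal(c(1, 2, 3, 10, 11, 12), c(0, 0, 0, 1, 1, 1))
  expect_equal(j$J, 1)
  two <- youden_optimal(c(1, 3), c(0, 1))
  expect_equal(two$cutoff, 2)
  set.seed(8)
  rand <- youden_optimal(rnorm(400), rbinom(400, 1, 0.5))
  expect_lt(rand$J, 0.2)
})

test_that("pearson_r recovers exact linear relationships", {
  x <- 1:10
  expect_equal(pearson_r(x, 2 * x + 1)$r, 1.0)
  expect_equal(pearson_r(x, -x)$r, -1.0)
  expect_error(pearson_r(x, rep(1, 10)), "constant")
  expect_error(pearson_r(1:2, 2:3), "3 complete")
})
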