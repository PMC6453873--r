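test_that("C-statistic handles perfect separation and full ties", {
  expect_equal(c_statistic(c(3, 4), c(1, 2))$auc, 1.0)
  expect_equal(c_statistic(c(1, 2), c(1, 2))$auc, 0.5)
  expect_error(c_statistic(numeric(0), 1:3), "non-empty")
})

test_that("C-statistic equals exhaustive pairwise counting, with ties", {
  set.seed(21)
  for (i in 1:40) {
    pos <- sample(round(rnorm(20, 1), 1))  # rounding induces ties
    neg <- sample(round(rnorm(20, 0), 1))
    expect_equal(c_statistic(pos, neg)$auc, brute_force_auc(pos, neg),
                 tolerance = 1e-14)
  }
})

test_that("AUC is invariant under strictly increasing transforms and flips under negation", {
  set.seed(22)
  pos <- round(rexp(30), 1)
  neg <- round(rexp(25, 1.5), 1)
  a <- c_statistic(pos, neg)$auc
  expect_equal(c_statistic(exp(pos), exp(neg))$auc, a)
  r <- rank(c(pos, neg), ties.method = "average")
  expect_equal(c_statistic(r[1:30], r[-(1:30)])$auc, a)
  expect_equal(c_statistic(-pos, -neg)$auc, 1 - a)
})

test_that("AUC result matches pROC and DeLong variance shrinks with n", {
  skip_if_not_installed("pROC")
  set.seed(23)
  scores <- c(rnorm(40, 1), rnorm(60))
  labels <- rep(c(1, 0), c(40, 60))
  ours <- c_statistic(scores[labels == 1], scores[labels == 0])
  ref <- pROC::roc(labels, scores, quiet = TRUE, direction = "<")
  expect_equal(ours$auc, as.numeric(pROC::auc(ref)), tolerance = 1e-12)
  ref_ci <- as.numeric(pROC::ci.auc(ref, method = "delong"))
  expect_equal(c(ours$ci_low, ours$ci_high), ref_ci[c(1, 3)], tolerance = 1e-9)

  set.seed(24)
  big <- c_statistic(rnorm(2000, 1), rnorm(2000))
  expect_lt(big$variance, ours$variance)
})

test_that("DeLong paired test: self-comparison is exactly null", {
  set.seed(25)
  s <- rnorm(50)
  y <- rep(c(TRUE, FALSE), 25)
  out <- delong_paired_test(s, s, y)
  expect_equal(out$z, 0)
  expect_equal(out$p, 1)
})

test_that("DeLong paired test agrees with pROC on correlated scores", {
  skip_if_not_installed("pROC")
  set.seed(26)
  y <- rep(c(TRUE, FALSE), c(40, 50))
  base <- rnorm(90) + y
  a <- base + rnorm(90, sd = 0.5)
  b <- base + rnorm(90, sd = 0.8)
  ours <- delong_paired_test(a, b, y)
  ref <- pROC::roc.test(pROC::roc(y, a, quiet = TRUE, direction = "<"),
                        pROC::roc(y, b, quiet = TRUE, direction = "<"),
                        method = "delong", paired = TRUE)
  expect_equal(ours$p, ref$p.value, tolerance = 1e-9)
  expect_equal(abs(ours$z), abs(as.numeric(ref$statistic)), tolerance = 1e-9)
})

test_that("DeLong variance of the AUC difference agrees with a paired bootstrap", {
  set.seed(27)
  y <- rep(c(TRUE, FALSE), c(25, 35))
  base <- rnorm(60) + 0.8 * y
  a <- base + rnorm(60, sd = 0.6)
  b <- 0.7 * base + rnorm(60, sd = 0.8)
  auc_of <- function(s, yy) c_statistic(s[yy], s[!yy])$auc
  boot <- replicate(2000, {
    i <- c(sample(which(y), replace = TRUE), sample(which(!y), replace = TRUE))
    auc_of(a[i], y[i]) - auc_of(b[i], y[i])
  })
  pl_a <- delong_paired_test(a, b, y)
  var_delong <- ((pl_a$auc_a - pl_a$auc_b) / pl_a$z)^2
  expect_equal(var_delong, stats::var(boot), tolerance = 0.15)
})

test_that("ROC curve spans (1,0) to (0,1) and its trapezoidal area equals the C-statistic", {
  set.seed(28)
  for (i in 1:25) {
    y <- c(rep(TRUE, 15), rep(FALSE, 20))
    s <- round(c(rnorm(15, 0.8), rnorm(20)), 1)
    curve <- roc_curve(s, y)
    expect_equal(curve$sensitivity[1], 1)
    expect_equal(curve$specificity[1], 0)
    expect_equal(curve$sensitivity[nrow(curve)], 0)
    expect_equal(curve$specificity[nrow(curve)], 1)
    expect_true(all(diff(curve$sensitivity) <= 0))
    expect_equal(attr(curve, "auc"), c_statistic(s[y], s[!y])$auc,
                 tolerance = 1e-12)
  }
})

test_that("label flip mirrors the curve area", {
  set.seed(29)
  y <- c(rep(TRUE, 10), rep(FALSE, 12))
  s <- rnorm(22) + y
  expect_equal(attr(roc_curve(s, !y), "auc"), 1 - attr(roc_curve(s, y), "auc"),
               tolerance = 1e-12)
})

test_that("the 'lower' orientation flips the comparison, not the data", {
  set.seed(30)
  y <- c(rep(TRUE, 10), rep(FALSE, 12))
  s <- rnorm(22) - y
  lo <- roc_curve(s, y, direction = "lower")
  expect_equal(attr(lo, "auc"), c_statistic(-s[y], -s[!y])$auc, tolerance = 1e-12)
})

test_that("Youden selection matches exhaustive search and breaks ties low", {
  set.seed(31)
  y <- c(rep(TRUE, 12), rep(FALSE, 14))
  s <- round(rnorm(26, ifelse(y, 0.8, 0)), 1)
  curve <- roc_curve(s, y)
  choice <- select_threshold(curve)
  grid <- vapply(unique(s), function(t) {
    mean(s[y] >= t) + mean(s[!y] < t) - 1
  }, numeric(1))
  expect_equal(choice$youden, max(grid), tolerance = 1e-12)

  sep <- roc_curve(c(1, 2, 3, 4), c(FALSE, FALSE, TRUE, TRUE))
  pick <- select_threshold(sep)
  expect_equal(pick$youden, 1)
  expect_equal(pick$threshold, 3)  # smallest cutpoint achieving J = 1
})

test_that("degenerate all-identical scores give J = 0 at a boundary operating point", {
  curve <- roc_curve(rep(2, 10), rep(c(TRUE, FALSE), 5))
  choice <- select_threshold(curve)
  expect_equal(choice$youden, 0)
  expect_true(all(c(choice$sensitivity, choice$specificity) %in% c(0, 1)))
})

test_that("fixed-threshold mode reports the operating point of the imposed cutpoint", {
  y <- c(rep(TRUE, 3), rep(FALSE, 3))
  s <- c(0.2, 0.5, 0.9, 0.7, 1.2, 2.0)
  curve <- roc_curve(s, y, direction = "lower")
  at <- select_threshold(curve, criterion = "fixed", threshold = 0.6)
  expect_equal(at$sensitivity, mean(s[y] <= 0.6))
  expect_equal(at$specificity, mean(s[!y] > 0.6))
})
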