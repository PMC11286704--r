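test_that("ICC(2,1) matches an independent ANOVA oracle", {
  # hand oracle on a 3 x 2 matrix via explicit mean squares
  m <- matrix(c(1, 3, 5, 2, 4, 6), nrow = 3)
  df <- data.frame(y = as.vector(m),
                   exam = factor(rep(1:3, 2)),
                   rater = factor(rep(1:2, each = 3)))
  aovt <- summary(stats::aov(y ~ exam + rater, data = df))[[1]]
  msr <- aovt["exam", "Mean Sq"]
  msc <- aovt["rater", "Mean Sq"]
  mse <- aovt["Residuals", "Mean Sq"]
  oracle <- (msr - mse) / (msr + (2 - 1) * mse + (2 / 3) * (msc - mse))
  r <- icc_2_1(m)
  expect_equal(r$estimate, oracle, tolerance = 1e-12)
  expect_equal(r$estimate, 8 / 9, tolerance = 1e-12)

  # identical columns with row variance: perfect agreement
  m2 <- cbind(c(3, 7, 11, 2), c(3, 7, 11, 2))
  r2 <- icc_2_1(m2)
  expect_equal(r2$estimate, 1)
  expect_equal(r2$label, "excellent")
  expect_error(icc_2_1(matrix(5, 4, 2)), "no variance")
  expect_error(icc_2_1(matrix(1:4, 2, 2)), ">= 3 exams")
})

test_that("ICC reduces to Pearson r for k = 2 with equal moments", {
  # with equal column means and variances the consistency form
  # (MSR - MSE) / (MSR + MSE) equals Pearson r exactly; the absolute-
  # agreement estimate differs only through the (k/n)(MSC - MSE) term and
  # converges to r as n grows
  x <- c(1, 2, 3, 4, 5, 6)
  y <- c(2, 1, 4, 3, 6, 5)  # same mean and variance by construction
  r <- icc_2_1(cbind(x, y))
  expect_equal((r$msr - r$mse) / (r$msr + r$mse), cor(x, y),
               tolerance = 1e-9)
  set.seed(31)
  xx <- rnorm(4000)
  yy <- 0.8 * xx + rnorm(4000, 0, 0.6)
  yy <- (yy - mean(yy)) / sd(yy) * sd(xx) + mean(xx)
  expect_equal(icc_2_1(cbind(xx, yy))$estimate, cor(xx, yy),
               tolerance = 2e-3)
})

test_that("ICC estimator recovers population values with little bias", {
  for (setting in list(c(9, 3, 0.9), c(3, 3, 0.5), c(sqrt(7), sqrt(3), 0.7))) {
    ests <- vapply(1:50, function(i) {
      icc_2_1(simulate_rating_table(200, setting[1], setting[2],
                                    seed = 5000 + i))$estimate
    }, numeric(1))
    expect_lt(abs(mean(ests) - setting[3]), 0.02)
  }
  # degenerate settings pin the estimator to its population value
  tbl <- simulate_rating_table(50, 9, 0, seed = 3)
  expect_identical(tbl[, 1], tbl[, 2])
  expect_equal(icc_2_1(tbl)$estimate, 1)
  expect_lte(icc_2_1(simulate_rating_table(200, 0, 5, seed = 4))$estimate,
             0.15)
})

test_that("Bland-Altman limits bracket the mean difference symmetrically", {
  x <- c(10, 20, 30, 40)
  expect_equal(bland_altman(x, x)$mean_diff, 0)
  expect_equal(unname(bland_altman(x, x)$loa), c(0, 0))

  set.seed(9)
  a <- rnorm(40, 100, 20)
  b <- a + rnorm(40, -3, 6)
  ba <- bland_altman(a, b)
  expect_equal(unname(mean(ba$loa)), ba$mean_diff, tolerance = 1e-12)
  expect_equal(unname(diff(ba$loa)), 2 * 1.96 * sd(a - b))

  # large-sample recovery of the population limits (-39.4, 30.4)
  set.seed(11)
  d <- rnorm(1e5, -4.5, 17.806)
  ba2 <- bland_altman(d, rep(0, 1e5))
  expect_lt(abs(ba2$loa[["lo"]] - (-39.4)), 0.5)
  expect_lt(abs(ba2$loa[["hi"]] - 30.4), 0.5)
  expect_error(bland_altman(1, numeric(0)))
})

test_that("Dice follows its definition and conventions", {
  a <- array(FALSE, dim = c(2, 16, 16))
  b <- a
  a[1, 1:2, 1:2] <- TRUE           # |a| = 4
  b[1, 1:2, 1:3] <- TRUE           # |b| = 6, overlap 4... adjust to 3
  b[1, 2, 1] <- FALSE              # |b| = 5, overlap 3
  b[1, 1, 4] <- TRUE               # |b| = 6, overlap 3
  expect_equal(dice(a, b), 2 * 3 / (4 + 6))
  expect_equal(dice(a, b), dice(b, a))
  expect_equal(dice(a, a), 1)
  empty <- array(FALSE, dim = c(2, 16, 16))
  expect_equal(as.numeric(dice(empty, empty)), 1)
  disj <- array(FALSE, dim = c(2, 16, 16))
  disj[2, 5, 5] <- TRUE
  expect_equal(dice(a, disj), 0)
  expect_error(dice(a, array(FALSE, dim = c(3, 16, 16))), "geometry")
})

test_that("logit transform and its boundary policy behave as declared", {
  expect_equal(logit(0.5), 0)
  expect_equal(logit(0.88), log(22 / 3))
  expect_equal(logit(0.88), 1.99243, tolerance = 1e-5)
  v <- c(0.1, 0.37, 0.88)
  expect_equal(logit(v) + logit(1 - v), rep(0, 3), tolerance = 1e-12)
  expect_error(logit(1), "clamp")
  expect_message(l <- logit(c(0.5, 1), clamp = TRUE), "clamped")
  expect_equal(l[2], log((1 - 1e-6) / 1e-6))
})

test_that("paired logit t-test is calibrated and guards degeneracy", {
  # constant logit shift -> zero-variance differences -> explicit error
  d1 <- c(0.7, 0.8, 0.9)
  d2 <- plogis(qlogis(d1) + 0.3)
  expect_error(paired_t_logit_dsc(d1, d2), "zero variance")

  # type-I error calibration at alpha = 0.05 under the null
  set.seed(21)
  rej <- vapply(1:400, function(i) {
    base <- rnorm(20, 1.8, 0.5)
    m1 <- plogis(base + rnorm(20, 0, 0.4))
    m2 <- plogis(base + rnorm(20, 0, 0.4))
    paired_t_logit_dsc(m1, m2)$p < 0.05
  }, logical(1))
  expect_gte(mean(rej), 0.02)
  expect_lte(mean(rej), 0.08)

  # power against a true shift of 0.3 sd 0.4 at n = 20, vs noncentral t
  ncp <- 0.3 / (0.4 * sqrt(2) / sqrt(20))
  tcrit <- qt(0.975, 19)
  power_oracle <- 1 - pt(tcrit, 19, ncp) + pt(-tcrit, 19, ncp)
  set.seed(22)
  rej2 <- vapply(1:200, function(i) {
    base <- rnorm(20, 1.8, 0.5)
    m1 <- plogis(base + rnorm(20, 0, 0.4))
    m2 <- plogis(base + 0.3 + rnorm(20, 0, 0.4))
    paired_t_logit_dsc(m1, m2)$p < 0.05
  }, logical(1))
  expect_gte(mean(rej2), 0.60)
  expect_lt(abs(mean(rej2) - power_oracle), 0.12)
})

test_that("simulated raters hit their target mutual Dice", {
  ph <- clean_phantom()
  blob <- ph$truth$confounder_masks$bladder
  rr <- simulate_raters(blob, target_dsc = 0.88, seed = 7)
  expect_gte(dice(rr$rater1, rr$rater2), 0.83)
  expect_lte(dice(rr$rater1, rr$rater2), 0.93)
  # determinism per seed
  rr2 <- simulate_raters(blob, target_dsc = 0.88, seed = 7)
  expect_identical(rr$rater1, rr2$rater1)
  # perfect agreement is exact
  p1 <- simulate_raters(blob, 1, seed = 1)
  expect_identical(p1$rater1, blob)
  expect_identical(p1$rater2, blob)
  expect_error(simulate_raters(array(FALSE, c(2, 16, 16)), 0.9), "nonempty")
  expect_error(simulate_raters(blob, 0.4), "target_dsc")
})

test_that("agreement reports compose the component statistics", {
  ph <- clean_phantom()
  ratings <- simulate_rating_table(20, 9, 3, seed = 13)
  pairs <- lapply(c(0.85, 0.9, 0.95), function(td)
    unname(simulate_raters(ph$truth$confounder_masks$bladder, td,
                           seed = round(td * 100))))
  rep <- build_report(ratings, mask_pairs = pairs)
  expect_true(rep$icc$estimate >= rep$icc$ci["lo"] &&
                rep$icc$estimate <= rep$icc$ci["hi"])
  expect_equal(unname(mean(rep$ba$loa)), rep$ba$mean_diff,
               tolerance = 1e-12)
  expect_true(all(rep$dsc$values >= 0 & rep$dsc$values <= 1))

  # self-agreement: ICC 1, zero differences, all DSC 1
  self <- build_report(cbind(ratings[, 1], ratings[, 1]),
                       mask_pairs = list(list(ph$truth$bowel_mask_pre,
                                              ph$truth$bowel_mask_pre)))
  expect_equal(self$icc$estimate, 1)
  expect_equal(self$ba$mean_diff, 0)
  expect_equal(self$dsc$values, 1)
  expect_error(build_report(ratings[1:2, ]), ">= 3")
})
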