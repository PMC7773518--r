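test_that("ICC distinguishes consistency from absolute agreement", {
  x <- c(60, 70, 80, 90, 75, 65)
  expect_equal(icc_pair(x, x, "consistency"), 1)
  expect_equal(icc_pair(x, x, "agreement"), 1)

  y <- x + 5
  expect_equal(icc_pair(x, y, "consistency"), 1, tolerance = 1e-12)
  expect_lt(icc_pair(x, y, "agreement"), 1)

  expect_error(icc_pair(1:2, 2:3), class = "sot_insufficient_data_error")
  expect_error(icc_pair(rep(5, 4), rep(5, 4)),
               class = "sot_undefined_statistic_error")
})

test_that("both ICC forms match the two-way ANOVA oracle to 1e-10", {
  withr::with_seed(21, {
    x <- rnorm(6, 50, 10)
    y <- x + rnorm(6, 2, 3)
  })
  d <- data.frame(score = c(x, y), subj = factor(rep(1:6, 2)),
                  dev = factor(rep(1:2, each = 6)))
  av <- summary(stats::aov(score ~ subj + dev, data = d))[[1]]
  MSR <- av["subj", "Mean Sq"]
  MSC <- av["dev", "Mean Sq"]
  MSE <- av["Residuals", "Mean Sq"]
  expect_equal(icc_pair(x, y, "consistency"), (MSR - MSE) / (MSR + MSE),
               tolerance = 1e-10)
  expect_equal(icc_pair(x, y, "agreement"),
               (MSR - MSE) / (MSR + MSE + (2 / 6) * (MSC - MSE)),
               tolerance = 1e-10)
})

test_that("consistency ignores a device offset; absolute agreement penalizes it", {
  withr::with_seed(22, {
    x <- rnorm(10, 70, 8)
    y <- x + rnorm(10, 0, 2)
  })
  shifted <- y + 7
  expect_equal(icc_pair(x, shifted, "consistency"),
               icc_pair(x, y, "consistency"), tolerance = 1e-12)
  expect_lt(icc_pair(x, shifted, "agreement"),
            icc_pair(x, y, "agreement"))
})

test_that("Pearson r and p match the textbook t-transform oracle", {
  x <- 1:5
  expect_equal(pearson_pair(x, 2 * x + 1)$r, 1)
  expect_equal(pearson_pair(x, -x)$r, -1)

  withr::with_seed(23, {
    a <- rnorm(20)
    b <- 0.5 * a + rnorm(20)
  })
  got <- pearson_pair(a, b)
  r_oracle <- sum((a - mean(a)) * (b - mean(b))) /
    sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  t_stat <- r_oracle * sqrt(18 / (1 - r_oracle^2))
  p_oracle <- 2 * stats::pt(-abs(t_stat), df = 18)
  expect_equal(got$r, r_oracle, tolerance = 1e-10)
  expect_equal(got$p, p_oracle, tolerance = 1e-10)

  # invariance under positive affine transforms of either variable
  expect_equal(pearson_pair(3 * a - 2, b)$r, got$r, tolerance = 1e-12)

  expect_error(pearson_pair(rep(1, 5), 1:5),
               class = "sot_undefined_statistic_error")
  expect_error(pearson_pair(1:2, 1:2),
               class = "sot_insufficient_data_error")
})

test_that("Bland-Altman statistics and translation equivariance", {
  x <- c(60, 70, 80)
  ba0 <- bland_altman(x, x)
  expect_equal(ba0$mean_diff, 0)
  expect_equal(ba0$loa_low, 0)
  expect_equal(ba0$loa_high, 0)

  ba <- bland_altman(c(0, 0), c(-1, 1))
  expect_equal(ba$mean_diff, 0)
  expect_equal(ba$loa_high, 1.96 * sqrt(2), tolerance = 1e-12)
  expect_equal(ba$loa_low, -1.96 * sqrt(2), tolerance = 1e-12)

  withr::with_seed(24, {
    a <- rnorm(10, 70, 5)
    b <- a + rnorm(10)
  })
  base <- bland_altman(a, b)
  shift <- bland_altman(a, b + 3)
  expect_equal(shift$mean_diff, base$mean_diff + 3, tolerance = 1e-12)
  expect_equal(shift$loa_low, base$loa_low + 3, tolerance = 1e-12)
  expect_equal(shift$loa_high, base$loa_high + 3, tolerance = 1e-12)

  expect_error(bland_altman(1, 2), class = "sot_insufficient_data_error")
})

test_that("interpretation bins follow the published thresholds", {
  expect_equal(interpret_icc(c(0.3, 0.6, 0.8, 0.95)),
               c("poor", "moderate", "good", "excellent"))
  expect_equal(interpret_icc(c(0.5, 0.75, 0.9)),
               c("moderate", "good", "excellent"))
  expect_equal(interpret_r(c(0.1, -0.45, 0.6, 0.8, 0.95)),
               c("negligible", "weak", "moderate", "strong", "very strong"))
  expect_equal(interpret_r(c(0.3, 0.5, 0.7, 0.9)),
               c("weak", "moderate", "strong", "very strong"))
  expect_equal(interpret_r(-0.506), "moderate")
})

test_that("agreement_stats bundles every statistic consistently", {
  withr::with_seed(25, {
    d <- tibble::tibble(ei = rnorm(12, 70, 8))
    d$eei <- d$ei + rnorm(12, 1, 4)
  })
  row <- agreement_stats(d, ei, eei)
  expect_equal(row$n, 12)
  expect_equal(row$icc_consistency, icc_pair(d$ei, d$eei, "consistency"))
  expect_equal(row$icc_absolute, icc_pair(d$ei, d$eei, "agreement"))
  expect_equal(row$pearson_r, pearson_pair(d$ei, d$eei)$r)
  expect_equal(row$ba_mean_diff, mean(d$eei - d$ei))
  expect_true(row$ba_loa_low <= row$ba_mean_diff)
  expect_true(row$ba_mean_diff <= row$ba_loa_high)
  expect_equal(row$icc_consistency_label,
               interpret_icc(row$icc_consistency))
  expect_equal(row$r_label, interpret_r(row$pearson_r))
})
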