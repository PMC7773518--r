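test_that("sway angles follow the inverse-sine model", {
  zero <- make_trace(rep(0, 100))
  th0 <- sway_angles(zero, height = 1.7)
  expect_equal(th0$theta_ant, 0)
  expect_equal(th0$theta_post, 0)

  # peaks of +/- 0.056 m at COG height 0.56 m give asin(0.1) each way
  ap <- palindrome_ap(0, n = 101)
  ap[3] <- 0.056; ap[99] <- 0.056; ap[51] <- -0.056
  th <- sway_angles(make_trace(ap), height = 1.0)
  expect_equal(th$theta_ant, asin(0.1) * 180 / pi, tolerance = 1e-12)
  expect_equal(th$theta_post, asin(0.1) * 180 / pi, tolerance = 1e-12)

  big <- make_trace(c(rep(0, 99), 0.6))
  expect_error(sway_angles(big, height = 1.0), class = "sot_domain_error")
})

test_that("the estimated equilibrium index is linear in combined sway and clamped", {
  h <- 0.56  # height 1.0 m
  score_at <- function(theta_total) {
    half <- theta_total / 2
    a <- h * sin(half * pi / 180)
    ap <- c(rep(c(a, -a), 49), a, -a)
    estimated_equilibrium_index(make_trace(ap), height = 1.0)
  }
  expect_identical(estimated_equilibrium_index(make_trace(rep(0, 100)),
                                               height = 1.7), 100)
  expect_equal(score_at(12.5), 0, tolerance = 1e-9)
  expect_equal(score_at(6.25), 50, tolerance = 1e-9)
  expect_equal(score_at(15), 0)   # beyond the limit: clamped at zero

  # monotone non-increasing in peak-to-peak AP sway, for fixed height
  scores <- vapply(seq(0.5, 12, length.out = 10), score_at, numeric(1))
  expect_true(all(diff(scores) <= 0))

  # invariant to ML content
  ap <- rep(c(0.01, -0.01), 50)
  withr::with_seed(8, ml <- rnorm(100, 0, 0.02))
  expect_equal(estimated_equilibrium_index(make_trace(ap, ml), 1.7),
               estimated_equilibrium_index(make_trace(ap), 1.7))
})

test_that("ellipse area matches the analytic bivariate-normal value", {
  same <- make_trace(rep(0.01, 100), rep(-0.02, 100))
  expect_equal(ellipse_area_95(same), 0)

  withr::with_seed(9, {
    tr <- make_trace(rnorm(1e5, 0, 0.01), rnorm(1e5, 0, 0.01), fs = 50)
  })
  area <- ellipse_area_95(tr)
  expect_lt(abs(area - pi * 5.991 * 1e-4) / (pi * 5.991 * 1e-4), 0.03)

  tr2 <- make_trace(2 * tr$ap[1:1000], 2 * tr$ml[1:1000])
  tr1 <- make_trace(tr$ap[1:1000], tr$ml[1:1000])
  expect_equal(ellipse_area_95(tr2), 4 * ellipse_area_95(tr1),
               tolerance = 1e-12)

  expect_error(ellipse_area_95(make_trace(c(0, 0.001))),
               class = "sot_degenerate_error")
})

test_that("path length sums consecutive step distances", {
  expect_equal(path_length(make_trace(rep(0.01, 50))), 0)
  two <- cop_trace(time = c(0, 0.02), ap = c(0, 0.03), ml = c(0, 0.04))
  expect_equal(path_length(two), 0.05)

  withr::with_seed(10, {
    tr <- make_trace(rnorm(500, 0, 0.01), rnorm(500, 0, 0.01))
  })
  oracle <- 0
  for (i in 2:500) {
    oracle <- oracle + sqrt((tr$ap[i] - tr$ap[i - 1])^2 +
                              (tr$ml[i] - tr$ml[i - 1])^2)
  }
  expect_equal(path_length(tr), oracle, tolerance = 1e-12)
})

test_that("DFA is scale-invariant and rejects degenerate series", {
  withr::with_seed(11, x <- rnorm(1000))
  expect_equal(dfa_alpha(3.7 * x), dfa_alpha(x), tolerance = 1e-9)
  expect_error(dfa_alpha(rnorm(10)), class = "sot_degenerate_error")
  expect_error(dfa_alpha(rep(1, 1000)), class = "sot_degenerate_error")
  expect_error(dfa_config(min_box = 2, poly_order = 1),
               class = "sot_validation_error")
})

test_that("the metric bundle is deterministic and order-symmetric", {
  zero <- make_trace(rep(0, 100))
  m0 <- compute_balance_metrics(zero, height = 1.7)
  expect_equal(m0$eei, 100)
  expect_equal(m0$ellipse_area_95, 0)
  expect_equal(m0$path_length, 0)
  expect_true(is.na(m0$dfa_alpha_ap))

  withr::with_seed(12, {
    tr <- make_trace(rnorm(1000, 0, 0.005), rnorm(1000, 0, 0.005))
  })
  m1 <- compute_balance_metrics(tr, height = 1.7)
  m2 <- compute_balance_metrics(tr, height = 1.7)
  expect_identical(m1, m2)

  rev_tr <- make_trace(rev(tr$ap), rev(tr$ml))
  mr <- compute_balance_metrics(rev_tr, height = 1.7)
  expect_equal(mr$ellipse_area_95, m1$ellipse_area_95, tolerance = 1e-12)
  expect_equal(mr$path_length, m1$path_length, tolerance = 1e-12)
})
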