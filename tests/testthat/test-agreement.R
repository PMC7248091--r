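# Passing-Bablok, Bland-Altman, within-threshold agreement.

test_that("Passing-Bablok recovers exact linear relations", {
  x <- c(5, 7, 9, 12, 15, 18)
  ident <- passing_bablok(tibble::tibble(reference_hb = x, device_hb = x))
  expect_equal(ident$slope, 1)
  expect_equal(ident$intercept, 0)
  lin <- passing_bablok(tibble::tibble(reference_hb = x, device_hb = 2 * x + 1))
  expect_equal(lin$slope, 2)
  expect_equal(lin$intercept, 1)
  expect_error(passing_bablok(tibble::tibble(reference_hb = c(1, 2),
                                             device_hb = c(1, 2))),
               class = "ptashb_input_error")
  expect_error(passing_bablok(tibble::tibble(reference_hb = rep(3, 4),
                                             device_hb = 1:4)),
               class = "ptashb_input_error")
})

test_that("Passing-Bablok matches the brute-force oracle on 25 random sets", {
  withr::with_seed(101, {
    for (rep in 1:25) {
      n <- sample(5:12, 1)
      x <- round(runif(n, 5, 20), 2)
      y <- round(1.03 * x - 0.2 + rnorm(n, 0, 0.6), 2)
      # CI ranks can be unavailable at the smallest n; only the point
      # estimators are under test here
      fit <- suppressWarnings(
        passing_bablok(tibble::tibble(reference_hb = x, device_hb = y)))
      oracle <- pb_oracle(x, y)
      expect_identical(fit$slope, oracle$slope)
      expect_identical(fit$intercept, oracle$intercept)
    }
  })
})

test_that("Passing-Bablok equivariance and CI containment", {
  big <- simulate_paired_hb(40, bias = -0.2, sd = 0.5, seed = 5)
  ci_fit <- passing_bablok(big)
  expect_true(ci_fit$slope_ci[1] <= ci_fit$slope && ci_fit$slope <= ci_fit$slope_ci[2])
  expect_true(ci_fit$intercept_ci[1] <= ci_fit$intercept &&
                ci_fit$intercept <= ci_fit$intercept_ci[2])
  # equivariance holds exactly on all-positive-slope data (the rank offset
  # K is tied to slopes below -1, so crossings would shift it)
  d <- tibble::tibble(
    reference_hb = c(5, 6.2, 7.9, 9.5, 11, 13, 15.5),
    device_hb = 1.03 * c(5, 6.2, 7.9, 9.5, 11, 13, 15.5) - 0.2 +
      c(0.02, -0.03, 0.01, 0.04, -0.02, 0.03, -0.01))
  fit <- passing_bablok(d)
  # scaling y scales slope and intercept
  fit3 <- passing_bablok(dplyr::mutate(d, device_hb = 3 * .data$device_hb))
  expect_equal(fit3$slope, 3 * fit$slope, tolerance = 1e-12)
  expect_equal(fit3$intercept, 3 * fit$intercept, tolerance = 1e-12)
  # swapping methods inverts the slope (odd slope count: exact)
  swapped <- passing_bablok(d, reference = device_hb, device = reference_hb)
  expect_equal(swapped$slope, 1 / fit$slope, tolerance = 1e-12)
  td <- tidy(fit)
  expect_identical(td$term, c("intercept", "slope"))
  expect_s3_class(autoplot(fit), "ggplot")
})

test_that("Bland-Altman formulas are internally consistent", {
  # all differences equal: bias d0, sd 0, degenerate LOA at d0
  same <- tibble::tibble(reference_hb = c(10, 12, 14), device_hb = c(10.5, 12.5, 14.5))
  ba0 <- bland_altman(same)
  expect_equal(ba0$bias, 0.5)
  expect_equal(ba0$sd, 0)
  expect_equal(ba0$loa, c(0.5, 0.5))
  # two-point arithmetic: diffs (-1, 1)
  two <- tibble::tibble(reference_hb = c(10, 10), device_hb = c(9, 11))
  ba2 <- bland_altman(two)
  expect_equal(ba2$bias, 0)
  expect_equal(ba2$sd, sqrt(2))
  expect_equal(ba2$loa, c(-1.96 * sqrt(2), 1.96 * sqrt(2)))
  # identity pairs: bias 0, sd 0
  x <- c(8, 11, 14)
  bai <- bland_altman(tibble::tibble(reference_hb = x, device_hb = x))
  expect_equal(c(bai$bias, bai$sd), c(0, 0))
  expect_error(bland_altman(same[1, ]), class = "ptashb_input_error")
})

test_that("Bland-Altman recovers a known injected bias", {
  d <- simulate_paired_hb(250, bias = 0.25, sd = 0.5, seed = 31)
  ba <- bland_altman(d)
  expect_lt(abs(ba$bias - 0.25), 1.96 * 0.5 / sqrt(250))
  expect_equal(ba$loa, c(ba$bias - 1.96 * ba$sd, ba$bias + 1.96 * ba$sd))
  expect_equal(ba$bias_ci, ba$bias + c(-1, 1) * 1.96 * ba$sd / sqrt(ba$n))
  expect_equal(ba$loa_lower_ci, ba$loa[1] + c(-1, 1) * 1.96 * ba$sd * sqrt(3 / ba$n))
  expect_s3_class(autoplot(ba), "ggplot")
})

test_that("within-threshold fraction is inclusive and monotone", {
  d <- tibble::tibble(reference_hb = rep(10, 4),
                      device_hb = 10 + c(0.5, 1.0, 1.5, 2.0))
  expect_equal(within_threshold_fraction(d), 50.0)
  ident <- tibble::tibble(reference_hb = c(9, 12), device_hb = c(9, 12))
  expect_equal(within_threshold_fraction(ident), 100.0)
  expect_equal(within_threshold_fraction(d, threshold = 0), 0.0)
  thresholds <- seq(0, 3, by = 0.25)
  fr <- vapply(thresholds, function(th) within_threshold_fraction(d, threshold = th),
               numeric(1))
  expect_true(all(diff(fr) >= 0))
})
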