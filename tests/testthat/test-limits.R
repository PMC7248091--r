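# Detection limits and precision summaries.

test_that("limit_of_blank: plain mean by default, CLSI rule on request", {
  expect_equal(limit_of_blank(c(0.001, 0.005, 0.006)), 0.004)
  expect_equal(limit_of_blank(rep(0, 10)), 0)
  v <- c(0.01, 0.02, 0.03)
  expect_equal(limit_of_blank(v, method = "mean_plus_1.645sd"),
               mean(v) + 1.645 * sd(v))
  expect_error(limit_of_blank(numeric(0)), class = "ptashb_input_error")
})

test_that("limit_of_detection is LoB + 1.645 * SD (n - 1 sample SD)", {
  expect_equal(limit_of_detection(0, values = rep(0.5, 5)), 0)
  # sd given directly (published-summary path)
  expect_equal(limit_of_detection(0.01, sd_low = 0.02), 0.01 + 1.645 * 0.02)
  # linearity in the SD of the low sample
  v <- c(0.02, 0.05, 0.03, 0.06, 0.04)
  lod1 <- limit_of_detection(0.01, values = v)
  lod3 <- limit_of_detection(0.01, values = 0.01 + 3 * v)
  expect_equal(lod3 - 0.01, 3 * (lod1 - 0.01), tolerance = 1e-12)
  expect_error(limit_of_detection(0.01, values = 0.3), class = "ptashb_input_error")
  expect_error(limit_of_detection(0.01), class = "ptashb_input_error")
})

test_that("limit_of_quantitation picks the adjacent pair nearest the target CV", {
  # only one pair: its nominal mean
  two <- tibble::tibble(nominal_hb = c(0.08, 0.12), cv = c(25, 15))
  expect_equal(limit_of_quantitation(two)$loq, 0.10)
  # tie between pairs resolves to the lower-concentration pair
  tie <- tibble::tibble(nominal_hb = c(0.05, 0.10, 0.15), cv = c(25, 15, 25))
  got <- limit_of_quantitation(tie)
  expect_equal(c(got$nominal_lo, got$nominal_hi), c(0.05, 0.10))
  # raw replicates route via summarize_replicates
  raw <- tibble::tibble(nominal_hb = rep(c(0.1, 0.2, 0.4), each = 4),
                        value = c(0.08, 0.12, 0.09, 0.11,
                                  0.19, 0.21, 0.20, 0.20,
                                  0.39, 0.41, 0.40, 0.40))
  summ <- summarize_replicates(raw)
  expect_equal(summ$cv, 100 * summ$sd / summ$mean)
  expect_s3_class(limit_of_quantitation(summ), "tbl_df")
  expect_error(limit_of_quantitation(two[1, ]), class = "ptashb_input_error")
})

test_that("summarize_replicates excludes non-positive means from CV", {
  d <- tibble::tibble(nominal_hb = rep(c(0, 0.1, 0.2), each = 3),
                      value = c(-0.01, 0.01, 0, 0.09, 0.11, 0.10,
                                0.19, 0.22, 0.20))
  s <- summarize_replicates(d)
  expect_true(is.na(s$cv[s$nominal_hb == 0]))
  expect_warning(loq <- limit_of_quantitation(s), "without a computable CV")
  expect_equal(loq$loq, 0.15)
})

test_that("detection_limits wrapper orders and flags the triple", {
  blank <- c(0.001, 0.002, 0.0015, 0.0025)
  low <- c(0.03, 0.05, 0.04, 0.045, 0.035)
  levels <- tibble::tibble(nominal_hb = c(0.0475, 0.095, 0.1188, 0.19),
                           cv = c(40, 25, 18, 12))
  dl <- detection_limits(blank, low, levels)
  expect_true(dl$ordered)
  expect_true(dl$lob <= dl$lod && dl$lod <= dl$loq)
  # deliberately disordered inputs warn and flag
  expect_warning(
    dl2 <- detection_limits(c(5, 5.1), c(0.01, 0.012), levels),
    "not ordered")
  expect_false(dl2$ordered)
})

test_that("precision summaries: intra and inter modes", {
  intra <- precision_summary(tibble::tibble(value = c(11.1, 11.2, 11.3, 11.2, 11.4)),
                             mode = "intra")
  expect_equal(intra$mean, 11.24)
  expect_equal(intra$cv, 100 * sd(c(11.1, 11.2, 11.3, 11.2, 11.4)) / 11.24)
  expect_equal(round(intra$cv, 2), 1.01)
  # identical values: CV exactly 0
  expect_equal(precision_summary(tibble::tibble(value = rep(16.4, 5)),
                                 mode = "intra")$cv, 0)
  # CV scale invariance
  v <- c(10.8, 11.1, 11.4, 10.9, 11.2)
  cv1 <- precision_summary(tibble::tibble(value = v), mode = "intra")$cv
  cv2 <- precision_summary(tibble::tibble(value = 3 * v), mode = "intra")$cv
  expect_equal(cv1, cv2, tolerance = 1e-12)
  # inter: total SD over all values, equal daily n enforced
  d <- tibble::tibble(day = rep(1:5, each = 5),
                      value = rep(c(11.1, 11.3, 11.2, 11.25, 11.15), each = 5))
  inter <- precision_summary(d, mode = "inter")
  expect_equal(inter$sd, sd(d$value))
  expect_identical(inter$n_days, 5L)
  bad <- tibble::tibble(day = c(1, 1, 2), value = c(11, 11.1, 11.2))
  expect_error(precision_summary(bad, mode = "inter"), class = "ptashb_input_error")
})
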