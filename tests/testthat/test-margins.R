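# Safety-margin fits: linear factors, upper bounds, caps, CSM curves.

test_that("lsf reproduces hand-computed fence and worst-case examples", {
  # all ratios equal: both methods return the common ratio
  p_const <- paired_samples(psar_e = rep(2, 20), psar_t = rep(3, 20))
  expect_equal(lsf(p_const, "worst_case")$value, 1.5)
  expect_equal(lsf(p_const, "outer_fence")$value, 1.5)

  # 99 ratios of 1.0 and one of 5.0: Q3 = 1, IQR = 0, fence = 1,
  # so the outlier is removed and the fence factor is exactly 1.0
  p_out <- paired_samples(psar_e = rep(1, 100), psar_t = c(rep(1, 99), 5))
  wc <- lsf(p_out, "worst_case")
  fence <- lsf(p_out, "outer_fence")
  expect_equal(wc$value, 5.0)
  expect_equal(fence$value, 1.0)
  expect_equal(fence$outliers_removed, 1L)

  # on realistic pairs the fence factor never exceeds the worst-case one
  p <- generate_joint_pairs(joint_spec(rho = 0.9, n_samples = 5000, seed = 1))
  expect_lte(lsf(p, "outer_fence")$value, lsf(p, "worst_case")$value)
})

test_that("worst-case lsf has zero underestimation on its own fit set", {
  p <- generate_joint_pairs(joint_spec(rho = 0.5, n_samples = 2000, seed = 3))
  expect_equal(underestimation_rate(lsf(p, "worst_case"), p), 0)
})

test_that("lsf input contracts", {
  expect_error(lsf(paired_samples(psar_e = rep(1, 5), psar_t = rep(1, 5))),
               "at least 10")
  expect_error(paired_samples(psar_e = c(1, -1), psar_t = c(1, 1)), "positive")
})

test_that("upper bound is the interpolated order-statistic quantile", {
  ub <- upper_bound(1:1000, level = 0.999)
  expect_equal(ub$value, 999.001)  # type-7 interpolation between x(999), x(1000)
  expect_equal(suppressWarnings(upper_bound(rep(2.5, 50))$value), 2.5)
  expect_warning(upper_bound(runif(100) + 1), "1000")
  # large lognormal sample matches the closed-form quantile within 2%
  set.seed(8)
  x <- rlnorm(1e6)
  expect_equal(upper_bound(x, 0.999)$value, qlnorm(0.999), tolerance = 0.02)
})

test_that("capped lsf is the pointwise min and dominates below UB/LSF", {
  m <- capped_lsf(1.36, 3.8)
  expect_equal(predict(m, 1.0), 1.36)
  expect_equal(predict(m, 10), 3.8)
  e <- seq(0.1, 8, by = 0.05)
  plain <- 1.36 * e
  expect_equal(predict(m, e), pmin(plain, 3.8))
  expect_true(all(predict(m, e) <= plain))
  expect_equal(predict(m, e)[e < 3.8 / 1.36], plain[e < 3.8 / 1.36])
})

test_that("margin application rejects non-positive estimates", {
  m <- capped_lsf(1.5, 4)
  expect_error(predict(m, 0), "positive")
  expect_error(predict(lsf(generate_joint_pairs(joint_spec(n_samples = 100,
                                                           seed = 1))), -2),
               "positive")
})

test_that("csm conditional columns integrate to one", {
  gmm <- list(weights = c(0.5, 0.5), means = rbind(c(1, 1), c(2, 2.2)),
              covs = list(diag(2) * 0.04, matrix(c(0.09, 0.04, 0.04, 0.09), 2)))
  t_axis <- seq(0.01, 6, by = 0.01)
  joint <- sarmargin:::gmm_density_grid(gmm, seq(0.5, 3, by = 0.01), t_axis)
  expect_true(all(joint >= 0))
  norm <- joint / (rowSums(joint) * 0.01)
  expect_equal(rowSums(norm) * 0.01, rep(1, nrow(norm)), tolerance = 1e-9)
})

test_that("csm is monotone in epsilon on a shared fit", {
  p <- generate_joint_pairs(joint_spec(rho = 0.9, n_samples = 2e4, seed = 6))
  f_hi <- csm(p, epsilon = 1e-2, seed = 2)
  f_mid <- csm(p, epsilon = 1e-3, seed = 2)
  f_lo <- csm(p, epsilon = 1e-4, seed = 2)
  expect_true(all(f_lo$corrected >= f_mid$corrected))
  expect_true(all(f_mid$corrected >= f_hi$corrected))
})

test_that("csm on a near-perfect estimator tracks the identity", {
  truth <- generate_joint_pairs(joint_spec(n_samples = 2e4, seed = 9))$psar_t
  p <- surrogate_estimator(truth, log_sd = 0.02, seed = 4)
  fit <- csm(p, epsilon = 0.001, seed = 5)
  qs <- quantile(p$psar_e, c(0.1, 0.9))
  e <- seq(qs[1], qs[2], length.out = 40)
  ratio <- predict(fit, e) / e
  # conditional 99.9% quantile of a 2% lognormal error is ~1.064 x estimate
  expect_true(all(ratio > 0.98))
  expect_true(all(ratio < 1.25))
})

test_that("csm epsilon and sample-size contracts hold", {
  p <- generate_joint_pairs(joint_spec(n_samples = 500, seed = 2))
  expect_warning(csm(p, epsilon = 0.01, seed = 1), "1000")
  p2 <- generate_joint_pairs(joint_spec(n_samples = 2000, seed = 2))
  expect_error(csm(p2, epsilon = 0.7), "epsilon")
  expect_error(csm(p2, epsilon = 0), "epsilon")
})

test_that("fitted margins round-trip bit-exactly through text", {
  p <- generate_joint_pairs(joint_spec(rho = 0.9, n_samples = 3000, seed = 4))
  fits <- list(lsf(p, "worst_case"), lsf(p, "outer_fence"),
               upper_bound(p, 0.999),
               capped_lsf(lsf(p, "outer_fence"), upper_bound(p, 0.999)),
               suppressWarnings(csm(p, epsilon = 0.001, seed = 1, k = 1:3)))
  for (fit in fits) {
    path <- withr::local_tempfile(fileext = ".txt")
    write_margin(fit, path)
    back <- read_margin(path)
    expect_equal(back, fit)
    e_test <- c(0.5, 1.3, 2.7)
    expect_identical(predict(back, e_test), predict(fit, e_test))
  }
})

test_that("underestimation rate extremes", {
  p <- generate_joint_pairs(joint_spec(n_samples = 1000, seed = 5))
  zero_margin <- capped_lsf(1e-9, 1e-9)
  expect_equal(underestimation_rate(zero_margin, p), 1)
  huge_margin <- capped_lsf(1e6, 1e6)
  expect_equal(underestimation_rate(huge_margin, p), 0)
})
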