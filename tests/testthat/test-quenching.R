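# A noiseless Stern-Volmer line must be recovered to machine precision.
test_that("fit_stern_volmer recovers an exact line", {
  q <- c(0, 2, 4, 6, 8, 10, 12, 16, 20) * 1e-5
  ksv <- 1.2e4
  tc <- titration_curve(q, 1000 / (1 + ksv * q), 297)
  fit <- fit_stern_volmer(tc)
  expect_equal(fit$ksv, ksv, tolerance = 1e-12)
  expect_equal(fit$intercept, 1, tolerance = 1e-10)
  expect_equal(fit$r2, 1, tolerance = 1e-12)
  expect_false(fit$degenerate)
  # Kq = Ksv / tau0 holds to rounding, for any tau0
  expect_equal(fit$kq * fit$tau0, fit$ksv, tolerance = 1e-12)
  fit2 <- fit_stern_volmer(tc, tau0 = 5.7e-9)
  expect_equal(fit2$kq * fit2$tau0, fit2$ksv, tolerance = 1e-12)
})

test_that("fit_stern_volmer warns on displaced intercepts and degenerate slopes", {
  q <- c(0, 1, 2, 3, 4) * 1e-5
  # an overstated F0 (e.g. unsubtracted background in the blank) scales
  # every F0/F value, displacing the free intercept from 1
  f <- 1000 / (1 + 1.2e4 * q)
  tc <- titration_curve(q, f, 297, f0 = 1200)
  expect_warning(fit_stern_volmer(tc), "intercept")
  # increasing fluorescence means Ksv <= 0
  tcd <- titration_curve(q, 1000 * (1 + 1e3 * q), 297)
  expect_warning(fit <- fit_stern_volmer(tcd), "degenerate")
  expect_true(fit$degenerate)
  expect_error(fit_stern_volmer(titration_curve(c(0, 1e-5), c(10, 5), 297)),
               "3 distinct")
})

test_that("classify_mechanism applies the diffusion threshold strictly", {
  expect_identical(classify_mechanism(2e10), "not_static")
  expect_identical(classify_mechanism(2e10 * (1 + 1e-9)), "static")
  expect_identical(classify_mechanism(1.05e12), "static")
  expect_identical(classify_mechanism(0), "not_static")
  expect_identical(classify_mechanism(3e10, threshold = 4e10), "not_static")
  expect_error(classify_mechanism(-1), "non-negative")
  expect_error(classify_mechanism(c(1, 2)), "single")
  expect_error(classify_mechanism(NA_real_), "finite")
})

test_that("fit_double_log recovers exact binding parameters", {
  q <- c(0, 2, 4, 6, 8, 10, 12, 16, 20) * 1e-5
  ka <- 4.13e4; n <- 1.16
  tc <- titration_curve(q, 1000 / (1 + ka * q^n), 297)
  fit <- fit_double_log(tc)
  expect_equal(fit$ka, ka, tolerance = 1e-9)
  expect_equal(fit$n, n, tolerance = 1e-12)
  expect_equal(fit$r2, 1, tolerance = 1e-12)
  expect_equal(fit$n_points, sum(q > 0))
})

test_that("fit_double_log is invariant to the logarithm base", {
  q <- c(0, 2, 5, 9, 14) * 1e-5
  tc <- titration_curve(q, 1000 / (1 + 3e4 * q^1.1), 297)
  f10 <- fit_double_log(tc, base = 10)
  fe <- fit_double_log(tc, base = exp(1))
  expect_equal(f10$ka, fe$ka, tolerance = 1e-9)
  expect_equal(f10$n, fe$n, tolerance = 1e-12)
})

test_that("fit_double_log rejects unquenched points with a warning", {
  q <- c(0, 1, 2, 3, 4, 5) * 1e-5
  f <- 1000 / (1 + 4e4 * q)
  f[2] <- 1001  # noise pushed one point above F0
  tc <- titration_curve(q, f, 297)
  expect_warning(fit <- fit_double_log(tc), "F >= F0")
  expect_equal(fit$n_points, 4)
  # all quenched points unusable -> error
  tc2 <- titration_curve(q, rep(1000, 6), 297, f0 = 999)
  expect_error(suppressWarnings(fit_double_log(tc2)), "fewer than 3")
})

test_that("quench_analysis combines both fits and the mechanism call", {
  q <- c(0, 2, 4, 6, 8, 10, 12, 16, 20) * 1e-5
  tc <- titration_curve(q, 1000 / (1 + 1.2e4 * q), 297)
  qa <- quench_analysis(tc)
  expect_equal(qa$ksv, 1.2e4, tolerance = 1e-9)
  expect_equal(qa$kq, 1.2e12, tolerance = 1e-9)
  expect_identical(qa$mechanism, "static")
  expect_equal(qa$temperature, 297)
})

test_that("noisy fits stay within the measured error envelope", {
  # 20 fixed seeds at study-like noise; bounds frozen from measured error
  # magnitudes (the noiseless case above pins exact recovery)
  r2 <- ksv_err <- n_err <- numeric(20)
  for (s in 1:20) {
    sc <- quench_scenario(noise_sigma = 0.005, seed = s)
    cv <- gen_titration(sc, 297, model = "stern_volmer")
    fit <- suppressWarnings(fit_stern_volmer(cv))
    r2[s] <- fit$r2
    ksv_err[s] <- abs(fit$ksv - attr(cv, "truth")$ksv) / attr(cv, "truth")$ksv
    cvb <- gen_titration(sc, 297, model = "binding")
    dl <- suppressWarnings(fit_double_log(cvb))
    n_err[s] <- abs(dl$n - attr(cvb, "truth")$n_sites)
  }
  expect_true(all(r2 > 0.98))
  expect_true(median(ksv_err) < 0.05)
  expect_true(median(n_err) < 0.05)
})
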