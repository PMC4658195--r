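test_that("sloped-baseline subtraction removes planted leak exactly", {
  t <- seq(0, 100, by = 0.2)
  # a trace that is exactly a line maps to zero
  expect_lt(max(abs(subtract_sloped_baseline(t, 3 - 0.4 * t, c(60, 100)))),
            1e-10)
  # zero-slope zero-offset trace is unchanged away from the signal
  sig <- ifelse(t > 10 & t < 30, exp(-(t - 10) / 4), 0)
  expect_equal(subtract_sloped_baseline(t, sig, c(60, 100)), sig,
               tolerance = 1e-12)
  # planted leak slope recovered within 1%
  g <- 0.37
  leaky <- sig + g * t + 5
  corr <- subtract_sloped_baseline(t, leaky, c(60, 100))
  resid_slope <- stats::coef(stats::lm(corr[t > 60] ~ t[t > 60]))[2]
  expect_lt(abs(resid_slope) / g, 0.01)
  expect_lt(abs(mean(corr[t >= 60])), 1e-10)
  expect_error(subtract_sloped_baseline(t, sig, c(60, 60.5)), "10 samples")
})

test_that("charge integration is trapezoidal", {
  t <- seq(0, 50, by = 0.1)
  expect_equal(integrate_charge(t, rep(0, length(t)), c(0, 50)), 0)
  rect <- ifelse(t >= 10 & t <= 20, 3, 0)
  expect_equal(integrate_charge(t, rect, c(10, 20.05)), 30, tolerance = 1e-10)
  expect_error(integrate_charge(t, rect, c(100, 120)), "outside")
})

test_that("non-saturating Q-V normalization divides by the same-cell reference", {
  v <- seq(-160, 40, by = 40)
  expect_equal(normalize_qv_nonsaturating(v, rep(5, 6), 5)$normalized,
               rep(1, 6))
  expect_equal(normalize_qv_nonsaturating(v, rep(0, 6), 5)$normalized,
               rep(0, 6))
  expect_error(normalize_qv_nonsaturating(v, rep(1, 6), 0))
})

test_that("gating decay fit starts after the peak and recovers known kinetics", {
  t <- seq(0, 120, by = 0.1)
  rise <- 1 - exp(-pmax(t - 10, 0) / 0.3)
  y <- rise * 4 * exp(-pmax(t - 10, 0) / 5)
  fit <- fit_gating_decay(t, y, c(10, 120))
  expect_equal(fit$tau_w, 5, tolerance = 0.05)
  # window starting at/after the peak is required implicitly: the fitted
  # decay ignores the clamp-settling rise before the |current| maximum
  expect_gt(fit$t0, 10)
})
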