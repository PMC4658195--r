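test_that("-dF/F0 has the dimming-positive sign convention", {
  t <- seq(0, 100, by = 0.5)
  expect_equal(compute_dff(t, rep(7, length(t)), c(0, 20)),
               rep(0, length(t)))
  f <- ifelse(t < 20, 100, 70)   # F0 = 100, drop to 70
  d <- compute_dff(t, f, c(0, 20))
  expect_equal(d[t >= 20][1], 0.30)
  expect_error(compute_dff(t, f - 100, c(0, 20)), "non-positive")
})

test_that("Gaussian low-pass filter has unit DC gain, no overshoot, and the right noise bandwidth", {
  dt <- 1   # ms -> 1 kHz sampling
  x <- rep(3, 500)
  expect_equal(lowpass_filter(x, 100, dt), x, tolerance = 1e-9)
  step <- c(rep(0, 250), rep(1, 250))
  ys <- lowpass_filter(step, 40, dt)
  expect_true(all(ys >= -1e-12 & ys <= 1 + 1e-12))   # kernel positivity
  set.seed(7)
  w <- stats::rnorm(200000)
  yf <- lowpass_filter(w, 40, dt)
  # equivalent noise bandwidth of a Gaussian |H|^2 relative to Nyquist
  sigma_ms <- sqrt(log(2)) / (2 * pi * 40) * 1000
  enbw <- 1 / (2 * sigma_ms / dt * sqrt(pi)) / (2 * pi) * 2 * pi  # fraction of fs
  expect_equal(stats::var(yf) / stats::var(w), enbw, tolerance = 0.1)
  expect_error(lowpass_filter(x, 600, dt), "Nyquist")
})

test_that("drift baselines are removed in both modes", {
  t <- seq(0, 2000, by = 2)
  regions <- list(c(0, 300), c(1600, 2000))
  line <- 2 + 0.003 * t
  expect_lt(max(abs(subtract_baseline(t, line, regions, "linear"))), 1e-9)
  # planted bleach tau = 2 s on a flat signal: residual drift < 5% of the
  # planted amplitude
  amp <- 5
  bl <- amp * exp(-t / 2000)
  corr <- subtract_baseline(t, bl, regions, "single_exponential")
  expect_lt(max(abs(corr)), 0.05 * amp)
  # linear mode on exponential drift: partial removal, no error
  expect_silent(subtract_baseline(t, bl, regions, "linear"))
})

test_that("fluorescence kinetics apply the single-exponential refit rule", {
  t <- seq(0, 300, by = 0.5)
  y1 <- 0.3 * (1 - exp(-t / 25))
  fit <- fit_fluor_kinetics(t, y1, c(0, 300))
  expect_true(fit$refit)
  expect_equal(fit$tau1, 25, tolerance = 0.01)
  expect_equal(fit$frac_fast, 1)
  # genuinely double-exponential response keeps both components
  y2 <- 0.25 * (1 - exp(-t / 8)) + 0.15 * (1 - exp(-t / 80))
  fit2 <- fit_fluor_kinetics(t, y2, c(0, 300))
  expect_false(fit2$refit)
  expect_equal(fit2$tau1, 8, tolerance = 0.05)
  expect_equal(fit2$frac_fast, 0.625, tolerance = 0.02)
})

test_that("lag is the abscissa crossing of the fitted exponential minus onset", {
  t <- seq(0, 100, by = 0.2)
  tau <- 12
  mk <- function(tc) ifelse(t < tc, 0, 0.3 * (1 - exp(-(t - tc) / tau)))
  # printed worked examples: crossings at 5 and 9 ms with onset 3 ms
  l1 <- extract_lag(t, mk(5), onset = 3)
  expect_true(l1$defined)
  expect_equal(l1$crossing, 5, tolerance = 1e-6)
  expect_equal(l1$lag, 2, tolerance = 1e-6)
  l2 <- extract_lag(t, mk(9), onset = 3)
  expect_equal(l2$lag, 6, tolerance = 1e-6)
  # response rising immediately at onset: zero lag
  l0 <- extract_lag(t, mk(3), onset = 3)
  expect_equal(l0$lag, 0, tolerance = 1e-6)
  # a fit that never crosses zero is flagged, not an error
  never <- 0.2 + 0.1 * exp(-t / tau)   # decays to +0.2, no zero crossing
  fit <- fit_fluor_kinetics(t, never, c(5, 100), refit_amp_frac = 1.01)
  ln <- extract_lag(t, never, onset = 3, fit = fit)
  expect_false(ln$defined)
  expect_true(is.na(ln$lag))
})
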