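test_that("morphological opening removes smooth background and keeps point sources", {
  fs <- 48
  xg <- matrix(rep(seq_len(fs), each = fs), fs)
  yg <- matrix(rep(seq_len(fs), times = fs), fs)
  flat <- matrix(2, fs, fs)
  expect_lt(max(abs(morphological_background(flat, radius = 5))), 1e-9)
  grad <- 10 * (xg + yg) / (2 * fs)
  spot <- 50 * exp(-((xg - 24)^2 + (yg - 24)^2) / (2 * 1.1^2))
  corr <- morphological_background(grad + spot, radius = 5)
  # interior pixels away from the spot (opening has edge effects within one
  # structuring-element radius of the border)
  interior <- xg > 6 & xg < fs - 6 & yg > 6 & yg < fs - 6
  away <- sqrt((xg - 24)^2 + (yg - 24)^2) > 8 & interior
  expect_lt(max(abs(corr[away])), 0.02 * diff(range(grad)))
  expect_equal(max(corr), max(spot), tolerance = 0.1)
  expect_error(morphological_background(flat, radius = 60), "field size")
})

test_that("spot detection recovers a planted grid and prunes close pairs", {
  expect_equal(nrow(detect_spots(matrix(0, 32, 32) + 1e-9)), 0)
  set.seed(13)
  fs <- 64
  xg <- matrix(rep(seq_len(fs), each = fs), fs)
  yg <- matrix(rep(seq_len(fs), times = fs), fs)
  pos <- as.matrix(expand.grid(seq(8, 56, by = 12), seq(8, 56, by = 12)))
  img <- matrix(stats::rnorm(fs * fs, 0, 1), fs)
  for (i in seq_len(nrow(pos))) {
    img <- img + 30 * exp(-((xg - pos[i, 1])^2 + (yg - pos[i, 2])^2) /
                            (2 * 1.1^2))
  }
  det <- detect_spots(img, threshold_k = 6, min_separation = 4)
  hits <- vapply(seq_len(nrow(pos)), function(i) {
    any((det$x - pos[i, 1])^2 + (det$y - pos[i, 2])^2 <= 4)
  }, logical(1))
  expect_gte(mean(hits), 0.95)
  expect_lte(nrow(det) - sum(hits), 1)
  # two spots closer than min_separation: only the brighter survives
  img2 <- matrix(0, 32, 32)
  img2 <- img2 + 20 * exp(-((xg[1:32, 1:32] - 15)^2 + (yg[1:32, 1:32] - 15)^2) / 2)
  img2 <- img2 + 10 * exp(-((xg[1:32, 1:32] - 17)^2 + (yg[1:32, 1:32] - 17)^2) / 2)
  det2 <- detect_spots(img2 + 1e-9, threshold_k = 3, min_separation = 5)
  expect_equal(nrow(det2), 1)
  expect_equal(unname(c(det2$x[1], det2$y[1])), c(15, 15))
})

test_that("aperture photometry reproduces the planted trace", {
  cam <- camera_model(read_sd = 0, offset = 50, gain = 2)
  pr <- voltage_protocol(-120, 120, step_onset = 100, step_duration = 200,
                         total_duration = 400, sample_interval = 2)
  tr <- simulate_blinking_trace("fluorophore-only", blink_model(0.02, 0.04),
                                pr, cam, photon_rate = 1000, seed = 7)
  # noise-free rendering: expected image, no photon or read noise
  mv <- render_movie(matrix(c(16, 16), 1), list(tr),
                     camera_model(read_sd = 0, offset = 0, gain = 1, qe = 1),
                     field_size = 32, background_photons = 0, seed = 8,
                     shot_noise = FALSE)
  ex <- extract_trace(mv, c(16, 16))
  expect_gt(stats::cor(ex$adu, tr$photon_mean), 0.999)
  # uniform frames give ~zero after annulus subtraction
  mvu <- mv; mvu$frames <- lapply(mv$frames, function(f) f * 0 + 7)
  exu <- extract_trace(mvu, c(16, 16))
  expect_lt(max(abs(exu$adu)), 1e-9)
  expect_warning(extract_trace(mv, c(2, 2)), "clipped")
})

test_that("autocorrelation matches the analytic telegraph form", {
  expect_error(fluctuation_test(autocorrelation(rnorm(100), 10), L = 0))
  bl <- blink_model(k_off = 0.03, k_on = 0.06)
  pr <- hold_protocol(V = 0, duration = 80000, dt = 2)
  tr <- simulate_blinking_trace("fluorophore-only", bl, pr, camera = NULL,
                                photon_rate = 100, seed = 17)
  ac <- autocorrelation(tr$photon_mean, max_lag = 40)
  expect_equal(ac$r[1], 1)
  expect_true(all(abs(ac$r) <= 1 + 1e-12))
  lags_ms <- ac$lags * 2
  # frame integration slightly distorts the first lags; compare lags 2-30
  # against exp(-(k_on+k_off) * lag) within ~3 SE of the ACF estimate
  theo <- exp(-(bl$k_off + bl$k_on) * lags_ms)
  se <- sqrt(1 / ac$n_samples * (1 + 2 * cumsum(theo^2)))
  idx <- 3:31
  expect_true(all(abs(ac$r[idx] - theo[idx]) < 3.5 * se[idx] + 0.02))
})

test_that("fluctuation test separates white noise from blinking", {
  pr <- hold_protocol(V = 0, duration = 8000, dt = 2)
  cam <- camera_model(frame_interval = 2, read_sd = 8, gain = 25)
  verdicts_white <- vapply(1:25, function(s) {
    tr <- simulate_blinking_trace("fluorophore-only", blink = NULL, pr, cam,
                                  photon_rate = 50, seed = 100 + s)
    fluctuation_test(autocorrelation(tr$adu, 20), L = 20)$fluctuating
  }, logical(1))
  expect_lte(mean(verdicts_white), 0.08)
  verdicts_blink <- vapply(1:25, function(s) {
    tr <- simulate_blinking_trace("fluorophore-only", blink_model(), pr, cam,
                                  photon_rate = 50, seed = 200 + s)
    fluctuation_test(autocorrelation(tr$adu, 20), L = 20)$fluctuating
  }, logical(1))
  expect_gte(mean(verdicts_blink), 0.9)
})

test_that("trace aggregation averages after per-trace baseline removal", {
  pr <- voltage_protocol(-120, 120, step_onset = 100, step_duration = 600,
                         total_duration = 900, sample_interval = 2)
  # deterministic step-shaped trace: the pre-pulse baseline is exactly flat,
  # so the per-trace linear baseline reduces to mean-centring on the window
  tms <- seq(1, 899, by = 2)
  tmpl <- structure(list(
    time = tms,
    adu = 500 - 300 * ifelse(tms < 100, 0, 1 - exp(-(tms - 100) / 50)),
    frame_interval = 2), class = "spot_trace")
  mean_tr <- aggregate_traces(list(tmpl, tmpl, tmpl),
                              baseline_regions = list(c(0, 100)))
  centred <- tmpl$adu - mean(tmpl$adu[tmpl$time < 100])
  expect_equal(mean_tr$adu, centred, tolerance = 1e-9)
  # pure-noise traces average to ~flat within the standard error
  set.seed(3)
  noise_traces <- lapply(1:40, function(i) {
    structure(list(time = tmpl$time, adu = stats::rnorm(length(tmpl$time)),
                   frame_interval = 2), class = "spot_trace")
  })
  m <- aggregate_traces(noise_traces)
  expect_lt(stats::sd(m$adu), 2.5 / sqrt(40))
  bad <- noise_traces[[1]]; bad$time <- bad$time + 1
  expect_error(aggregate_traces(list(noise_traces[[2]], bad)), "timing")
})

test_that("averaging 67 responding traces recapitulates the macroscopic step response", {
  sch <- reference_parameters("arclight")
  sch$temperature_C <- 14
  cam <- camera_model()
  pr <- voltage_protocol(-120, 120, step_onset = 200, step_duration = 600,
                         total_duration = 1000, sample_interval = 1)
  resp <- lapply(1:67, function(i) {
    simulate_blinking_trace(sch, blink_model(), pr, cam, step = 120,
                            photon_rate = 100, seed = 42000 + i)
  })
  avg <- aggregate_traces(resp, baseline_regions = list(c(0, 200),
                                                        c(900, 1000)))
  filt <- lowpass_filter(avg$adu, 100, avg$frame_interval)
  trj <- propagate_occupancy(sch, pr, 120)
  model <- fluorescence_signal(trj, sch)
  mf <- stats::approx(trj$time, model - model[1], avg$time)$y
  # fluorophore blinking is the dominant noise in single-molecule means; at
  # the committed blink configuration 67 traces give correlations ~0.9
  expect_gt(stats::cor(filt, mf), 0.85)
  # the mean dims during the pulse and recovers after it
  in_pulse <- avg$time > 400 & avg$time < 800
  pre <- avg$time < 200
  expect_lt(mean(filt[in_pulse]), mean(filt[pre]) - 3 * stats::sd(filt[pre]))
})
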