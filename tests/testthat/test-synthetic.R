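test_that("macroscopic recordings are seed-deterministic and noise-free equals the model", {
  sch <- four_state()
  pr <- short_on(steps = c(-40, 40), dt = 0.5)
  a <- simulate_macroscopic_recording(sch, pr, seed = 5)
  b <- simulate_macroscopic_recording(sch, pr, seed = 5)
  expect_identical(a$sweeps, b$sweeps)
  c2 <- simulate_macroscopic_recording(sch, pr, seed = 6)
  expect_false(identical(a$sweeps, c2$sweeps))
  nf <- simulate_macroscopic_recording(sch, pr, n_molecules = 1e6,
                                       noise = no_noise(), seed = 5,
                                       clamp_tau = 0)
  trj <- propagate_occupancy(sch, pr, step = 40)
  expect_equal(nf$sweeps[["40"]]$gating, gating_current(trj, sch, 1e6),
               tolerance = 1e-12)
  expect_equal(nf$sweeps[["40"]]$fluorescence,
               fluorescence_signal(trj, sch) * 1000, tolerance = 1e-12)
  expect_equal(nf$sweeps[["40"]]$vm, trj$voltage)
})

test_that("the estimated membrane potential settles with the clamp time constant", {
  sch <- four_state()
  pr <- short_on(steps = 40, dt = 0.1)
  rec <- simulate_macroscopic_recording(sch, pr, noise = no_noise(), seed = 1,
                                        clamp_tau = 0.5)
  sw <- rec$sweeps[["40"]]
  rise <- (sw$vm - (-120)) / 160
  # the settling is single-exponential with the requested time constant
  sel <- sw$time >= 20 & sw$time < 22 & rise < 0.999
  slope <- stats::coef(stats::lm(log(1 - rise[sel]) ~ sw$time[sel]))[2]
  expect_equal(unname(-1 / slope), 0.5, tolerance = 0.05)
  # settled within ten time constants
  i0 <- which(sw$time >= 20)[1]
  expect_gt(rise[i0 + 50], 0.99)
})

test_that("pulse-train protocol generates the action-potential-like frequency", {
  pr <- pulse_train_protocol(n_pulses = 8, pulse_ms = 5, gap_ms = 10)
  expect_equal(train_frequency(pr), 1000 / 15)   # ~67 Hz
  seg <- protocol_segments(pr)
  expect_equal(sum(seg$V > pr$holding), 8)
  expect_equal(unique(diff(seg$t0[seg$V > pr$holding])), 15)
  v <- voltage_trace(pr)
  expect_setequal(unique(v), c(-70, 30))
})

test_that("blinking traces obey telegraph statistics", {
  bl <- blink_model(k_off = 0.025, k_on = 0.05)
  pr <- hold_protocol(V = 0, duration = 60000, dt = 2)
  tr <- simulate_blinking_trace("fluorophore-only", bl, pr, camera = NULL,
                                photon_rate = 100, seed = 9)
  # dark fraction = k_off/(k_on + k_off) within 3 SE (rough SE from the
  # number of independent dwell cycles)
  dark_frac_obs <- 1 - mean(tr$photon_mean) / max(tr$photon_mean)
  p_dark <- bl$k_off / (bl$k_on + bl$k_off)
  n_cycles <- 60000 * bl$k_off * bl$k_on / (bl$k_off + bl$k_on)
  se <- sqrt(p_dark * (1 - p_dark) / n_cycles)
  expect_lt(abs(dark_frac_obs - p_dark), 3.5 * se)
  # same seed reproduces bit-identically
  tr2 <- simulate_blinking_trace("fluorophore-only", bl, pr, camera = NULL,
                                 photon_rate = 100, seed = 9)
  expect_identical(tr$photon_mean, tr2$photon_mean)
})

test_that("camera converts photons to ADU with gain and offset", {
  pr <- hold_protocol(V = 0, duration = 4000, dt = 2)
  cam <- camera_model(frame_interval = 2, gain = 30, read_sd = 5,
                      offset = 100, qe = 0.9)
  tr <- simulate_blinking_trace("fluorophore-only", blink = NULL, pr, cam,
                                photon_rate = 50, seed = 3)
  mu <- 50 * 2 * 0.9
  expect_equal(mean(tr$adu), 30 * mu + 100, tolerance = 0.02)
  # non-blinking emitter: autocorrelation consistent with white noise
  ac <- autocorrelation(tr$adu, max_lag = 20)
  expect_lt(fluctuation_test(ac, L = 20)$n_exceed, 4)
})

test_that("rendered movies place PSFs at the requested positions", {
  cam <- camera_model(read_sd = 0, offset = 0, gain = 1)
  pr <- hold_protocol(V = 0, duration = 20, dt = 2)
  tr <- simulate_blinking_trace("fluorophore-only", NULL, pr, cam,
                                photon_rate = 2000, seed = 2)
  mv <- render_movie(matrix(c(20, 31), 1), list(tr), cam, field_size = 48,
                     background_photons = 0, seed = 4)
  for (f in mv$frames) {
    pk <- which(f == max(f), arr.ind = TRUE)[1, ]   # (row, col) = (y, x)
    expect_lt(sqrt(sum((pk - c(31, 20))^2)), 1.5)
  }
  # zero spots: a pure background stack
  mv0 <- render_movie(matrix(numeric(0), 0, 2), list(), cam, field_size = 32,
                      background_photons = 3, seed = 4, n_frames = 4)
  expect_length(mv0$frames, 4)
  expect_lt(max(vapply(mv0$frames, max, numeric(1))), 3 * 4.5 * 2)
  # overlapping spots warn but do not fail
  expect_warning(
    render_movie(rbind(c(10, 10), c(11, 11)), list(tr, tr), cam,
                 field_size = 32, seed = 1),
    "min_separation")
})
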