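test_that("rate matrix follows the single-barrier voltage law", {
  sch <- four_state()
  Vt <- sch$Vt
  for (V in c(-160, 0, 140)) {
    Q <- rate_matrix(sch, V)
    expect_equal(rowSums(Q), rep(0, 4), tolerance = 1e-12)
    expect_true(all(Q[upper.tri(Q) | lower.tri(Q)] >= 0))
    # hand computation of the stated rate law for transition 1
    expect_equal(Q[1, 2], sch$k_f0[1] * exp(sch$z[1] * 0.5 * V / Vt))
    expect_equal(Q[2, 1], sch$k_b0[1] * exp(-sch$z[1] * 0.5 * V / Vt))
    # voltage-independent transitions keep their 0 mV rates
    expect_equal(Q[2, 3], sch$k_f0[2])
    expect_equal(Q[4, 3], sch$k_b0[3])
  }
  # forward/backward ratio of transition 1 over a 300 mV span
  r_hi <- transition_rates(sch, 140)
  r_lo <- transition_rates(sch, -160)
  expect_equal((r_hi$kf[1] / r_hi$kb[1]) / (r_lo$kf[1] / r_lo$kb[1]),
               exp(sch$z[1] * 300 / Vt), tolerance = 1e-10)
})

test_that("zero gating charge removes all voltage dependence", {
  sch <- kinetic_scheme(c(0.1, 0.2, 0.3), c(0.3, 0.2, 0.1), z = c(0, 0, 0),
                        brightness = c(1, 1, 1, 0))
  expect_equal(rate_matrix(sch, 123.4), rate_matrix(sch, 0))
  expect_equal(steady_state(sch, -80), steady_state(sch, 80))
})

test_that("extreme voltages overflow with an informative error", {
  sch <- two_state()
  expect_error(transition_rates(sch, 1e6), "transition 1")
})

test_that("steady state is the detailed-balance chain equilibrium", {
  sch <- two_state(kf = 0.2, kb = 0.1, z = 1)
  # V1/2 of a two-state scheme: K(V1/2) = 1
  vhalf <- -sch$Vt / sch$z[1] * log(sch$k_f0[1] / sch$k_b0[1])
  expect_equal(steady_state(sch, vhalf), c(0.5, 0.5), tolerance = 1e-12)
  # uniform occupancy when every K_i = 1
  schu <- kinetic_scheme(c(0.1, 0.1, 0.1), c(0.1, 0.1, 0.1), z = c(0, 0, 0),
                         brightness = rep(1, 4))
  expect_equal(steady_state(schu, 37), rep(0.25, 4), tolerance = 1e-12)
  # strong depolarization pushes all occupancy past a charged transition 1
  schz <- kinetic_scheme(c(0.1, 0.1, 0.1), c(0.1, 0.1, 0.1), z = c(1, 0, 0),
                         brightness = rep(1, 4))
  expect_lt(steady_state(schz, 400)[1], 1e-6)
  expect_equal(steady_state(sch, 1e3)[2], 1, tolerance = 1e-10)
})

test_that("normalized Q-V and dim-state F-V are congruent when only transition 1 is charged", {
  # algebraic identity: both equal K1*a/(1 + K1*a) up to scale,
  # a = 1 + K2 + K2*K3, checked numerically on a 31-point grid
  sch <- four_state()
  vg <- seq(-160, 140, by = 10)
  q <- vapply(vg, function(v) {
    p <- steady_state(sch, v)
    sum(p[2:4])           # charge moved (z on transition 1 only)
  }, numeric(1))
  fdim <- vapply(vg, function(v) steady_state(sch, v)[4], numeric(1))
  qn <- (q - min(q)) / (max(q) - min(q))
  fn <- (fdim - min(fdim)) / (max(fdim) - min(fdim))
  K2 <- sch$k_f0[2] / sch$k_b0[2]
  K3 <- sch$k_f0[3] / sch$k_b0[3]
  a <- 1 + K2 + K2 * K3
  K1 <- (sch$k_f0[1] / sch$k_b0[1]) * exp(sch$z[1] * vg / sch$Vt)
  ref <- K1 * a / (1 + K1 * a)
  refn <- (ref - min(ref)) / (max(ref) - min(ref))
  expect_equal(qn, refn, tolerance = 1e-9)
  expect_equal(fn, refn, tolerance = 1e-9)
})

test_that("occupancy propagation is exact and normalized", {
  sch <- four_state()
  pr <- short_on(steps = c(-120, 40))
  # step equal to the holding potential: occupancies constant
  trj <- propagate_occupancy(sch, pr, step = -120)
  expect_lt(max(abs(sweep(trj$occupancy, 2, trj$occupancy[1, ]))), 1e-11)
  # every row sums to one
  trj <- propagate_occupancy(sch, pr, step = 40)
  expect_lt(max(abs(rowSums(trj$occupancy) - 1)), 1e-9)
  expect_true(all(trj$occupancy >= -1e-12 & trj$occupancy <= 1 + 1e-12))
  # a long fixed-voltage stretch converges to the steady state
  prl <- hold_protocol(V = 40, duration = 3000, dt = 5)
  trl <- propagate_occupancy(sch, prl, initial = c(1, 0, 0, 0))
  expect_equal(trl$occupancy[nrow(trl$occupancy), ], steady_state(sch, 40),
               tolerance = 1e-8)
})

test_that("gating current integrates to the equilibrium charge displacement and conserves charge", {
  sch <- four_state()
  # the OFF spike decays with a sub-millisecond time constant, so the
  # conservation check needs fine sampling to keep quadrature error small
  pr <- voltage_protocol(-120, 40, step_onset = 20, step_duration = 1200,
                         total_duration = 4000, sample_interval = 0.02)
  trj <- propagate_occupancy(sch, pr, step = 40)
  I <- gating_current(trj, sch, n_molecules = 1)
  tt <- trj$time
  trapz <- function(sel) sum(diff(tt[sel]) *
                               (head(I[sel], -1) + tail(I[sel], -1)) / 2)
  q_on <- trapz(tt >= 20 & tt < 1220)
  dp <- steady_state(sch, 40) - steady_state(sch, -120)
  expect_equal(q_on, sch$z[1] * sum(dp[2:4]), tolerance = 2e-3)
  # ON + OFF integrates to zero (charge conservation; segments integrated
  # separately because the current is discontinuous at the voltage edges)
  q_off <- trapz(tt >= 1220)
  expect_lt(abs(q_on + q_off) / abs(q_on), 5e-3)
  # step to holding: identically zero current
  trj0 <- propagate_occupancy(sch, pr, step = -120)
  expect_lt(max(abs(gating_current(trj0, sch, 1e6))), 1e-6)
})

test_that("two-state gating current decays single-exponentially with tau = 1/(kf+kb)", {
  sch <- two_state(kf = 0.08, kb = 0.04, z = 1)
  pr <- short_on(steps = 20, dt = 0.1)
  trj <- propagate_occupancy(sch, pr, step = 20)
  I <- gating_current(trj, sch, 1)
  sel <- trj$time > 20.05 & trj$time < 220
  fit <- fit_exp_decay(trj$time[sel], I[sel], n_components = 1)
  r <- transition_rates(sch, 20)
  expect_equal(fit$components$tau, 1 / (r$kf[1] + r$kb[1]), tolerance = 1e-4)
})

test_that("fluorescence is occupancy-weighted brightness", {
  sch <- four_state()
  pr <- short_on(steps = 40)
  trj <- propagate_occupancy(sch, pr, step = 40)
  # uniform brightness: constant trace
  schu <- sch; schu$brightness <- rep(2, 4)
  expect_equal(fluorescence_signal(trj, schu), rep(2, length(trj$time)),
               tolerance = 1e-12)
  # brightness (1,1,1,0): F = 1 - p_dim
  schd <- sch; schd$brightness <- c(1, 1, 1, 0)
  expect_equal(fluorescence_signal(trj, schd), 1 - trj$occupancy[, 4],
               tolerance = 1e-12)
  # depolarization dims the reference-style parameterization
  Fl <- fluorescence_signal(trj, sch)
  expect_lt(Fl[length(Fl) - 760], Fl[1])  # late in pulse vs baseline
  # end-of-pulse fractional change agrees with the steady-state prediction
  F0 <- steady_state_fluorescence(sch, -120)
  Fss <- steady_state_fluorescence(sch, 40)
  i_end <- max(which(trj$time < 220))
  expect_equal(-(Fl[i_end] - F0) / F0, -(Fss - F0) / F0, tolerance = 0.01)
})

test_that("scale and shift helpers act on a single transition", {
  sch <- four_state()
  fast <- scale_transition(sch, 1, forward = 10, backward = 20)
  expect_equal(fast$k_f0[1] / sch$k_f0[1], 10)
  expect_equal(fast$k_b0[1] / sch$k_b0[1], 20)
  expect_equal(fast$k_f0[-1], sch$k_f0[-1])
  sh <- shift_transition(sch, 1, 30)
  K <- function(s, V) (s$k_f0[1] / s$k_b0[1]) * exp(s$z[1] * V / s$Vt)
  expect_equal(K(sh, 30), K(sch, 0), tolerance = 1e-12)
})
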