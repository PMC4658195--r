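test_that("a noise-free sweep family yields sensible, normalized curves", {
  sch <- fast_four_state()
  pr <- on_protocol(sample_interval = 0.5, step_levels = seq(-120, 120, 40))
  rec <- simulate_macroscopic_recording(sch, pr, noise = no_noise(), seed = 1)
  cv <- build_curves(rec)
  expect_s3_class(cv$boltzmann, "boltzmann_fit")
  # noiseless Q-V strictly increasing for z1 > 0
  expect_true(all(diff(cv$qv$charge) > 0))
  expect_true(all(cv$qv$norm > -0.05 & cv$qv$norm < 1.05))
  # F-V normalized with the Q-V scaling factors superimposes on the Q-V
  m <- cv$fv$norm - cv$qv$norm
  expect_lt(max(abs(m[cv$qv$norm > 0.05])), 0.05)
  # single-step family gives single-row curves
  pr1 <- on_protocol(sample_interval = 0.5, step_levels = 40)
  rec1 <- simulate_macroscopic_recording(sch, pr1, noise = no_noise(), seed = 1)
  cv1 <- build_curves(rec1, qv_normalization = "total-charge",
                      reference_total_charge = cv$total_charge)
  expect_equal(nrow(cv1$qv), 1)
  expect_equal(nrow(cv1$tau_fluor), 1)
})

test_that("ON and OFF families of the same scheme conserve charge", {
  sch <- fast_four_state()
  onr <- simulate_macroscopic_recording(
    sch, on_protocol(0.5, seq(-120, 120, 40)), noise = no_noise(), seed = 1)
  onc <- build_curves(onr)
  offr <- simulate_macroscopic_recording(
    sch, off_protocol(0.5, c(-160, -120, -80, 40)), noise = no_noise(),
    seed = 1)
  offc <- build_curves(offr, qv_normalization = "total-charge",
                       reference_total_charge = onc$total_charge)
  # conservation: the charge returned by stepping from +40 mV holding to
  # -160 mV equals the charge the ON family moved in reaching +40 mV
  q_off_sat <- offc$qv$norm[offc$qv$voltage == -160]
  q_on_at_40 <- onc$qv$norm[onc$qv$voltage == 40]
  expect_equal(q_off_sat, q_on_at_40, tolerance = 0.05)
  # zero charge at the step equal to holding
  expect_lt(abs(offc$qv$norm[offc$qv$voltage == 40]), 0.01)
})

test_that("curve tables export to CSV", {
  sch <- four_state()
  rec <- simulate_macroscopic_recording(
    sch, on_protocol(1, c(-40, 40)), noise = no_noise(), seed = 1)
  cv <- build_curves(rec, qv_normalization = "total-charge",
                     reference_total_charge = 1)
  d <- withr::local_tempdir()
  paths <- write_curves(cv, d)
  expect_true(all(file.exists(file.path(
    d, c("qv.csv", "fv.csv", "tau_gating.csv", "tau_fluor.csv", "lag.csv")))))
  qv <- utils::read.csv(file.path(d, "qv.csv"))
  expect_equal(qv$voltage, cv$qv$voltage)
})
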