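test_that("reference variants derive from the committed ArcLight scheme", {
  arc <- reference_parameters("arclight")
  expect_s3_class(arc, "kinetic_scheme")
  expect_equal(arc$n_states, 4)
  expect_equal(arc$temperature_C, 19)
  # the dim state sits past the last (fluorescence) transition
  expect_lt(arc$brightness[4], arc$brightness[1])
  # only transition 1 carries gating charge by default
  expect_true(arc$z[1] != 0)
  expect_equal(arc$z[-1], c(0, 0))
  arcl <- reference_parameters("arclightning")
  expect_equal(arcl$k_f0[1] / arc$k_f0[1], 10)
  expect_equal(arcl$k_b0[1] / arc$k_b0[1], 20)
  # voltage-midpoint shifts keep the F-V ordering R217E < R217Q < R217R
  vhalf_ss <- function(s) {
    vg <- seq(-250, 250, 1)
    q <- vapply(vg, function(v) sum(steady_state(s, v)[-1]), numeric(1))
    vg[which.min(abs(q - (max(q) + min(q)) / 2))]
  }
  expect_gt(vhalf_ss(reference_parameters("R217R")), vhalf_ss(arc))
  expect_lt(vhalf_ss(reference_parameters("R217E")), vhalf_ss(arc))
  th <- reference_parameters("three_state_arclight")
  expect_equal(th$n_states, 3)
  expect_equal(th$k_f0[1], arc$k_f0[1])
  expect_equal(th$k_f0[2], arc$k_f0[3])
})

test_that("steady-state dF/F0 span is computed about the F-V midpoint", {
  sch <- four_state()
  sp <- steady_state_dff_span(sch)
  expect_true(sp$F_low > sp$F_high)
  expect_gt(sp$span_pct, 0)
  # the midpoint voltage halves the fluorescence drop
  Fmid <- steady_state_fluorescence(sch, sp$V_mid)
  vg <- seq(-200, 200, 0.5)
  Fv <- vapply(vg, function(v) steady_state_fluorescence(sch, v), numeric(1))
  expect_lt(abs(Fmid - (max(Fv) + min(Fv)) / 2), 0.01)
})

test_that("calibration returns an already-satisfying scheme unchanged in effect", {
  # with every target already met, the calibrated scheme must stay at (or
  # return to) an objective no worse than the committed optimum
  sch <- reference_parameters("arclight")
  cal <- calibrate_reference(sch, maxit = 10)
  expect_lt(abs(cal$k_f0[1] / sch$k_f0[1] - 1), 0.02)
  expect_lt(abs(cal$k_b0[1] / sch$k_b0[1] - 1), 0.02)
  expect_lt(abs(cal$z[1] / sch$z[1] - 1), 0.02)
})

test_that("the committed ArcLightning file matches the x10/x20 derivation", {
  p <- system.file("extdata", "reference_arclightning.json",
                   package = "gevikin", mustWork = TRUE)
  committed <- read_scheme(p)
  derived <- reference_parameters("arclightning")
  expect_equal(committed$k_f0, derived$k_f0, tolerance = 1e-12)
  expect_equal(committed$k_b0, derived$k_b0, tolerance = 1e-12)
  expect_equal(committed$z, derived$z)
  expect_equal(committed$brightness, derived$brightness)
})
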