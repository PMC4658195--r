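# Small schemes and protocols used across the test files.

two_state <- function(kf = 0.2, kb = 0.1, z = 1, delta = 0.5,
                      brightness = c(1, 0)) {
  kinetic_scheme(kf, kb, z, delta, brightness, name = "two_state_test")
}

four_state <- function() {
  kinetic_scheme(k_f0 = c(0.05, 0.5, 0.04), k_b0 = c(0.25, 0.25, 0.008),
                 z = c(1.1, 0, 0), brightness = c(1, 1, 1, 0.35),
                 name = "four_state_test")
}

# variant whose fluorescence transition equilibrates well within a 200 ms
# pulse, for tests that rely on charge/fluorescence saturation in-sweep
fast_four_state <- function() {
  kinetic_scheme(k_f0 = c(0.05, 0.5, 0.2), k_b0 = c(0.25, 0.25, 0.05),
                 z = c(1.1, 0, 0), brightness = c(1, 1, 1, 0.35),
                 name = "fast_four_state_test")
}

hold_protocol <- function(V = 0, duration = 200, dt = 0.5) {
  voltage_protocol(V, V, step_onset = 0, step_duration = duration,
                   total_duration = duration, sample_interval = dt)
}

short_on <- function(steps = c(-40, 40), dt = 0.2) {
  voltage_protocol(-120, steps, step_onset = 20, step_duration = 200,
                   sample_interval = dt)
}
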