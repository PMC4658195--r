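#' Piecewise-constant voltage-step protocol
#'
#' A protocol is a family of sweeps sharing a holding potential, step onset,
#' step duration and tail level; each sweep differs only in its step level.
#' Time is in ms, voltage in mV; windows are half-open `[start, end)`.
#'
#' @param holding holding potential, mV.
#' @param step_levels step potentials, mV (non-empty).
#' @param step_onset step onset time, ms.
#' @param step_duration step duration, ms.
#' @param tail tail potential after the step (default: back to holding), mV.
#' @param total_duration sweep length, ms (default: onset + duration + 150 ms).
#' @param sample_interval sampling interval, ms.
#' @return object of class `voltage_protocol`.
#' @export
voltage_protocol <- function(holding, step_levels, step_onset = 20,
                             step_duration = 200, tail = holding,
                             total_duration = step_onset + step_duration + 150,
                             sample_interval = 0.2) {
  stopifnot(length(step_levels) >= 1, sample_interval > 0,
            total_duration >= step_onset + step_duration)
  structure(list(
    holding = holding, step_levels = as.numeric(step_levels),
    step_onset = step_onset, step_duration = step_duration,
    tail = tail, total_duration = total_duration,
    sample_interval = sample_interval, segments = NULL
  ), class = "voltage_protocol")
}

#' Standard depolarizing ('on') step family
#'
#' Holding -120 mV, 200 ms steps from -140 to +120 mV in 20 mV increments —
#' the standard activation protocol for cut-open oocyte gating-current
#' recordings from ArcLight.
#'
#' @param sample_interval sampling interval, ms.
#' @param step_levels step potentials, mV.
#' @export
on_protocol <- function(sample_interval = 0.2,
                        step_levels = seq(-140, 120, by = 20)) {
  voltage_protocol(-120, step_levels, step_onset = 20, step_duration = 200,
                   sample_interval = sample_interval)
}

#' Standard hyperpolarizing ('off') step family
#'
#' Holding +40 mV, 200 ms steps from -160 to +40 mV in 20 mV increments.
#'
#' @inheritParams on_protocol
#' @export
off_protocol <- function(sample_interval = 0.2,
                         step_levels = seq(-160, 40, by = 20)) {
  voltage_protocol(40, step_levels, step_onset = 20, step_duration = 200,
                   sample_interval = sample_interval)
}

#' Action-potential-like pulse-train protocol
#'
#' A train of brief depolarizing pulses separated by a resting interval, used
#' to test whether an indicator recovers to baseline between stimuli. With the
#' default 5 ms pulses separated by 10 ms the train runs at approximately
#' 67 Hz.
#'
#' @param n_pulses number of pulses.
#' @param pulse_ms pulse duration, ms.
#' @param gap_ms inter-pulse interval at rest, ms.
#' @param holding resting potential, mV.
#' @param amplitude pulse amplitude above rest, mV (default 100).
#' @param lead_ms time at rest before the first pulse, ms.
#' @param sample_interval sampling interval, ms.
#' @return a `voltage_protocol` with explicit segments and a
#'   `train_frequency_hz` field equal to `1000 / (pulse_ms + gap_ms)`.
#' @export
pulse_train_protocol <- function(n_pulses = 10, pulse_ms = 5, gap_ms = 10,
                                 holding = -70, amplitude = 100, lead_ms = 20,
                                 sample_interval = 0.2) {
  stopifnot(n_pulses >= 1, pulse_ms > 0, gap_ms > 0)
  period <- pulse_ms + gap_ms
  t0 <- lead_ms + (seq_len(n_pulses) - 1) * period
  seg <- data.frame(
    t0 = c(0, as.vector(rbind(t0, t0 + pulse_ms))),
    V = c(holding, rep(c(holding + amplitude, holding), n_pulses))
  )
  total <- lead_ms + n_pulses * period + gap_ms
  p <- voltage_protocol(holding, holding + amplitude, step_onset = lead_ms,
                        step_duration = pulse_ms, total_duration = total,
                        sample_interval = sample_interval)
  p$segments <- seg
  p$train_frequency_hz <- 1000 / period
  p
}

#' Stimulation frequency of a pulse-train protocol
#' @param protocol a [pulse_train_protocol()].
#' @return frequency in Hz.
#' @export
train_frequency <- function(protocol) {
  if (is.null(protocol$train_frequency_hz)) {
    stop("protocol has no pulse train")
  }
  protocol$train_frequency_hz
}

#' Voltage segments of one sweep
#'
#' @param protocol a `voltage_protocol`.
#' @param step step level (mV) selecting the sweep; ignored for explicit
#'   segment protocols.
#' @return data.frame with columns `t0`, `t1`, `V` covering `[0, total)`.
#' @export
protocol_segments <- function(protocol, step = protocol$step_levels[1]) {
  if (!is.null(protocol$segments)) {
    s <- protocol$segments
    return(data.frame(t0 = s$t0, t1 = c(s$t0[-1], protocol$total_duration),
                      V = s$V))
  }
  t0 <- c(0, protocol$step_onset, protocol$step_onset + protocol$step_duration)
  V <- c(protocol$holding, step, protocol$tail)
  seg <- data.frame(t0 = t0, t1 = c(t0[-1], protocol$total_duration), V = V)
  seg <- seg[seg$t1 > seg$t0, , drop = FALSE]
  rownames(seg) <- NULL
  seg
}

#' Sample time grid of a protocol
#' @param protocol a `voltage_protocol`.
#' @export
protocol_times <- function(protocol) {
  seq(0, protocol$total_duration, by = protocol$sample_interval)
}

#' Command voltage evaluated on the sample grid
#'
#' @inheritParams protocol_segments
#' @param times optional time vector, ms (default: the protocol grid).
#' @export
voltage_trace <- function(protocol, step = protocol$step_levels[1],
                          times = protocol_times(protocol)) {
  seg <- protocol_segments(protocol, step)
  idx <- findInterval(times, seg$t0, rightmost.closed = FALSE)
  idx[idx < 1L] <- 1L
  idx[idx > nrow(seg)] <- nrow(seg)
  seg$V[idx]
}
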