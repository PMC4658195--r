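#' Instrument noise model for macroscopic recordings
#'
#' Defaults emulate a low-noise cut-open oocyte clamp with photodiode
#' fluorescence detection: white current noise, a linear leak conductance, a
#' small residual (uncompensated) capacitive transient at voltage edges,
#' white fluorescence noise and an optional bleach baseline.
#'
#' @param gating_sd white-noise SD on the current trace (e0/ms units).
#' @param leak_slope leak conductance slope (current units per mV).
#' @param cap_amp residual capacitive-transient amplitude per 100 mV edge.
#' @param cap_tau capacitive-transient time constant, ms (> 0).
#' @param fluor_sd white-noise SD on the fluorescence trace (photodiode units).
#' @param bleach `"none"`, `"linear"` or `"single_exponential"`.
#' @param bleach_rate fractional loss per second for linear bleach.
#' @param tau_bleach bleach time constant, ms, for exponential bleach.
#' @return object of class `noise_model`.
#' @export
noise_model <- function(gating_sd = 150, leak_slope = 20, cap_amp = 2000,
                        cap_tau = 0.3, fluor_sd = 2,
                        bleach = c("none", "linear", "single_exponential"),
                        bleach_rate = 0.02, tau_bleach = 2000) {
  bleach <- match.arg(bleach)
  stopifnot(gating_sd >= 0, fluor_sd >= 0, cap_tau > 0, tau_bleach > 0)
  structure(list(gating_sd = gating_sd, leak_slope = leak_slope,
                 cap_amp = cap_amp, cap_tau = cap_tau, fluor_sd = fluor_sd,
                 bleach = bleach, bleach_rate = bleach_rate,
                 tau_bleach = tau_bleach),
            class = "noise_model")
}

#' A noise model with every artifact switched off
#' @export
no_noise <- function() {
  noise_model(gating_sd = 0, leak_slope = 0, cap_amp = 0, fluor_sd = 0,
              bleach = "none")
}

#' Simulate a macroscopic gating-current + fluorescence recording
#'
#' One simulated "cell": for every step level of the protocol, the
#' deterministic occupancy trajectory is converted to a gating-current sweep
#' (scaled by `n_molecules`, plus leak, residual capacitive transients and
#' white noise), a fluorescence sweep (scaled to photodiode units, with
#' optional bleach baseline and white noise) and an estimated
#' membrane-potential trace (the command filtered by a single-exponential
#' clamp settling time). With an all-zero noise model the traces equal the
#' deterministic model outputs exactly.
#'
#' @param scheme a [kinetic_scheme()].
#' @param protocol a [voltage_protocol()].
#' @param n_molecules number of indicator molecules (scales the current).
#' @param noise a [noise_model()].
#' @param seed integer seed; identical seeds give identical recordings.
#' @param fluor_scale photodiode units per unit relative fluorescence.
#' @param clamp_tau membrane-charging time constant for the estimated
#'   membrane potential, ms.
#' @return object of class `vcf_recording`; `sweeps` is a list keyed by step
#'   level with elements `time`, `gating`, `fluorescence`, `vm`.
#' @export
simulate_macroscopic_recording <- function(scheme, protocol,
                                           n_molecules = 1e6,
                                           noise = noise_model(), seed = 1,
                                           fluor_scale = 1000,
                                           clamp_tau = 0.15) {
  set.seed(seed)
  sweeps <- list()
  for (s in protocol$step_levels) {
    traj <- propagate_occupancy(scheme, protocol, s)
    tt <- traj$time
    I <- gating_current(traj, scheme, n_molecules)
    Fr <- fluorescence_signal(traj, scheme) * fluor_scale
    V <- traj$voltage
    g <- I + noise$leak_slope * V
    if (noise$cap_amp > 0) {
      seg <- protocol_segments(protocol, s)
      if (nrow(seg) > 1) {
        for (k in 2:nrow(seg)) {
          dV <- seg$V[k] - seg$V[k - 1]
          if (dV != 0) {
            rel <- tt - seg$t0[k]
            g <- g + ifelse(rel >= 0,
                            noise$cap_amp * dV / 100 * exp(-rel / noise$cap_tau),
                            0)
          }
        }
      }
    }
    if (noise$gating_sd > 0) g <- g + stats::rnorm(length(g), 0, noise$gating_sd)
    Fr <- switch(noise$bleach,
      none = Fr,
      linear = Fr * (1 - noise$bleach_rate * tt / 1000),
      single_exponential = Fr * exp(-tt / noise$tau_bleach))
    if (noise$fluor_sd > 0) Fr <- Fr + stats::rnorm(length(Fr), 0, noise$fluor_sd)
    # single-pole RC settling of the clamp
    vm <- V
    if (clamp_tau > 0) {
      a <- exp(-protocol$sample_interval / clamp_tau)
      vm <- stats::filter(V * (1 - a), a, method = "recursive",
                          init = V[1])
      vm <- as.numeric(vm)
    }
    sweeps[[as.character(s)]] <- list(time = tt, gating = g,
                                      fluorescence = Fr, vm = vm)
  }
  structure(list(protocol = protocol, sweeps = sweeps,
                 scheme_name = scheme$name, n_molecules = n_molecules,
                 noise = noise, seed = seed, fluor_scale = fluor_scale,
                 temperature_C = scheme$temperature_C),
            class = "vcf_recording")
}

#' Two-state fluorophore blinking (telegraph) model
#'
#' Millisecond-scale bright/dark switching of the GFP moiety, independent of
#' the voltage-sensing chain. The autocorrelation of the resulting intensity
#' decays as `exp(-(k_on + k_off) * lag)` and the equilibrium dark fraction
#' is `k_off / (k_on + k_off)`.
#'
#' @param k_off dark-entry rate, 1/ms.
#' @param k_on dark-exit rate, 1/ms.
#' @param dark_brightness relative brightness of the dark state (default 0).
#' @return object of class `blink_model`.
#' @export
blink_model <- function(k_off = 0.025, k_on = 0.05, dark_brightness = 0) {
  stopifnot(k_off > 0, k_on > 0, dark_brightness >= 0, dark_brightness <= 1)
  structure(list(k_off = k_off, k_on = k_on,
                 dark_brightness = dark_brightness), class = "blink_model")
}

#' EMCCD-like camera model
#'
#' Photons are Poisson-drawn per frame, amplified by the EM gain
#' (scaled-Poisson approximation of the electron-multiplication register) and
#' read out with Gaussian noise and a fixed offset, in ADU.
#'
#' @param frame_interval frame interval, ms (500 Hz default).
#' @param qe quantum efficiency (0-1).
#' @param gain EM gain, ADU per photoelectron.
#' @param read_sd read noise SD, ADU.
#' @param offset camera offset, ADU.
#' @param pixel_size pixel size, um.
#' @param psf_sigma PSF standard deviation, pixels.
#' @return object of class `camera_model`.
#' @export
camera_model <- function(frame_interval = 2, qe = 0.9, gain = 30,
                         read_sd = 10, offset = 100, pixel_size = 0.24,
                         psf_sigma = 1.1) {
  stopifnot(gain > 0, offset >= 0, frame_interval > 0, qe > 0, qe <= 1)
  structure(list(frame_interval = frame_interval, qe = qe, gain = gain,
                 read_sd = read_sd, offset = offset, pixel_size = pixel_size,
                 psf_sigma = psf_sigma), class = "camera_model")
}

# Fraction of each frame spent at each brightness level, integrated exactly
# from a jump path: returns per-frame mean of `values[state]`.
.frame_average <- function(jump_t, jump_state, values, frame_edges) {
  nf <- length(frame_edges) - 1L
  out <- numeric(nf)
  # piecewise-constant integral via the cumulative integral at frame edges
  tt <- c(jump_t, max(frame_edges[nf + 1L], jump_t[length(jump_t)]) + 1)
  cum <- c(0, cumsum(values[jump_state] * diff(tt)))
  cum_at <- function(x) {
    i <- findInterval(x, tt)
    i[i < 1L] <- 1L
    cum[i] + values[jump_state[pmin(i, length(jump_state))]] * (x - tt[i])
  }
  ca <- cum_at(frame_edges)
  diff(ca) / diff(frame_edges)
}

#' Simulate a single-molecule intensity trace with blinking and camera noise
#'
#' Per-frame mean photon count = conformational brightness x blink state x
#' photon flux x frame interval, integrated exactly over each frame from the
#' stochastic paths; the camera model then converts photons to ADU. Passing
#' `scheme = "fluorophore-only"` drops the voltage-sensing chain (an isolated
#' GFP domain: constant unit conformational brightness).
#'
#' @param scheme a [kinetic_scheme()] or `"fluorophore-only"`.
#' @param blink a [blink_model()], or `NULL` for a non-blinking emitter.
#' @param protocol a [voltage_protocol()] (sets duration; ignored for
#'   voltage when `scheme = "fluorophore-only"`).
#' @param camera a [camera_model()], or `NULL` for noise-free photon means
#'   (useful for testing the telegraph statistics).
#' @param step step level of the sweep, mV.
#' @param photon_rate bright-state photon flux at unit brightness,
#'   photons/ms.
#' @param seed integer seed.
#' @return object of class `spot_trace`: `time` (frame mid-times, ms),
#'   `adu` (intensity), `photon_mean` (noise-free per-frame means),
#'   `frame_interval`.
#' @export
simulate_blinking_trace <- function(scheme, blink, protocol, camera,
                                    step = protocol$step_levels[1],
                                    photon_rate = 100, seed = 1) {
  set.seed(seed)
  dt <- if (!is.null(camera)) camera$frame_interval else 2
  edges <- seq(0, protocol$total_duration, by = dt)
  nf <- length(edges) - 1L
  mid <- edges[-1] - dt / 2
  # conformational brightness per frame
  if (identical(scheme, "fluorophore-only")) {
    conf <- rep(1, nf)
  } else {
    paths <- gillespie_sample(scheme, protocol, step, n_molecules = 1,
                              seed = sample.int(.Machine$integer.max, 1))
    p <- paths$paths[[1]]
    conf <- .frame_average(p$t, p$state, scheme$brightness, edges)
  }
  # blink telegraph per frame (state 1 = bright, 2 = dark)
  if (!is.null(blink)) {
    bl_scheme <- kinetic_scheme(blink$k_off, blink$k_on, z = 0,
                                brightness = c(1, blink$dark_brightness),
                                name = "blink")
    bp <- gillespie_sample(bl_scheme, protocol, step, n_molecules = 1,
                           seed = sample.int(.Machine$integer.max, 1))$paths[[1]]
    bfac <- .frame_average(bp$t, bp$state,
                           c(1, blink$dark_brightness), edges)
  } else bfac <- rep(1, nf)
  mu <- conf * bfac * photon_rate * dt
  if (is.null(camera)) {
    adu <- mu
  } else {
    ne <- stats::rpois(nf, mu * camera$qe)
    adu <- camera$gain * ne +
      stats::rnorm(nf, 0, camera$read_sd) + camera$offset
  }
  structure(list(time = mid, adu = adu, photon_mean = mu,
                 frame_interval = dt, step = step, seed = seed),
            class = "spot_trace")
}

#' Render a TIRF-like movie of point emitters
#'
#' Each frame places a Gaussian point-spread function at every spot position
#' scaled by that frame's photon mean, adds a smooth background gradient,
#' then applies the camera model pixel-wise (Poisson photons, EM gain, read
#' noise, offset). Spots closer than `min_separation` trigger a warning.
#'
#' @param positions n x 2 matrix of spot centres (x, y in pixels, 1-based).
#' @param traces list of [simulate_blinking_trace()] results (photon means
#'   are used), one per spot, equal frame counts.
#' @param camera a [camera_model()].
#' @param field_size edge length in pixels.
#' @param background_photons background level, photons/pixel/frame, applied
#'   as a corner-to-corner gradient from 0.5x to 1.5x this value.
#' @param min_separation warn if two spots are closer than this (pixels).
#' @param seed integer seed.
#' @param n_frames frame count when `traces` is empty (background-only stack).
#' @param shot_noise draw photons from the Poisson counting distribution
#'   (`FALSE` renders the noise-free expected image, useful for operator
#'   round-trip checks).
#' @return object of class `movie_stack`: `frames` (list of matrices, ADU),
#'   `positions`, `camera`, `frame_interval`.
#' @export
render_movie <- function(positions, traces, camera, field_size = 64,
                         background_photons = 5, min_separation = 4,
                         seed = 1, n_frames = NULL, shot_noise = TRUE) {
  set.seed(seed)
  positions <- matrix(as.numeric(positions), ncol = 2)
  stopifnot(nrow(positions) == length(traces))
  if (nrow(positions) >= 1 &&
      (any(positions < 1) || any(positions > field_size))) {
    stop("spot positions must lie inside the field")
  }
  if (nrow(positions) >= 2) {
    d <- as.matrix(stats::dist(positions))
    diag(d) <- Inf
    if (min(d) < min_separation) {
      warning(sprintf("spots closer than min_separation (%.2f px)", min(d)))
    }
  }
  nf <- if (length(traces)) length(traces[[1]]$photon_mean) else (n_frames %||% 16L)
  xg <- matrix(rep(seq_len(field_size), each = field_size), field_size)
  yg <- matrix(rep(seq_len(field_size), times = field_size), field_size)
  bg <- background_photons * (0.5 + (xg + yg - 2) / (2 * (field_size - 1)))
  psf <- lapply(seq_len(nrow(positions)), function(i) {
    k <- exp(-((xg - positions[i, 1])^2 + (yg - positions[i, 2])^2) /
               (2 * camera$psf_sigma^2))
    k / sum(k)
  })
  frames <- vector("list", nf)
  for (f in seq_len(nf)) {
    mu <- bg
    for (i in seq_along(psf)) {
      mu <- mu + traces[[i]]$photon_mean[f] * psf[[i]]
    }
    ne <- if (shot_noise) {
      matrix(stats::rpois(length(mu), as.vector(mu) * camera$qe), field_size)
    } else mu * camera$qe
    frames[[f]] <- camera$gain * ne +
      matrix(stats::rnorm(length(mu), 0, camera$read_sd), field_size) +
      camera$offset
  }
  structure(list(frames = frames, positions = positions, camera = camera,
                 frame_interval = camera$frame_interval, seed = seed),
            class = "movie_stack")
}

#' Write a movie stack as a multi-page TIFF
#'
#' Float-32 TIFF, one page per frame (intensities rescaled to 0-1), with
#' the frame interval and intensity scale recorded in a JSON sidecar
#' (`<path>.json`).
#'
#' @param movie a [render_movie()] result.
#' @param path output file.
#' @export
write_movie_tiff <- function(movie, path) {
  mx <- max(vapply(movie$frames, max, numeric(1)), 1)
  pages <- lapply(movie$frames, function(f) f / mx)
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  jsonlite::write_json(list(frame_interval_ms = movie$frame_interval,
                            scale_adu = mx, n_frames = length(pages)),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a multi-page TIFF written by [write_movie_tiff()]
#' @param path TIFF file.
#' @return list with `frames` (matrices, ADU) and `frame_interval` (ms, or
#'   NA when no sidecar is present).
#' @export
read_movie_tiff <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  fi <- NA_real_; sc <- 1
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    fi <- meta$frame_interval_ms %||% NA_real_
    sc <- meta$scale_adu %||% 1
  }
  list(frames = lapply(pages, function(p) p * sc), frame_interval = fi)
}

#' Average repeated recordings of the same protocol
#'
#' Gating-current and fluorescence sweeps are routinely signal-averaged over
#' repeated stimulus presentations; this averages the per-sweep traces of
#' recordings that share a protocol (white noise shrinks by 1/sqrt(n)).
#'
#' @param recordings list of [simulate_macroscopic_recording()] results with
#'   identical protocols.
#' @return a `vcf_recording` whose traces are the per-sample means.
#' @export
average_recordings <- function(recordings) {
  stopifnot(length(recordings) >= 1)
  out <- recordings[[1]]
  for (s in names(out$sweeps)) {
    for (ch in c("gating", "fluorescence", "vm")) {
      acc <- out$sweeps[[s]][[ch]]
      for (r in recordings[-1]) acc <- acc + r$sweeps[[s]][[ch]]
      out$sweeps[[s]][[ch]] <- acc / length(recordings)
    }
  }
  out$n_averaged <- length(recordings)
  out
}
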