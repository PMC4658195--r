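#' Normalize an F-V curve with the scaling factors of the same cell's Q-V
#'
#' The Q-V Boltzmann fit supplies the shape parameters (V1/2, z); the F-V
#' limits are then obtained by linear regression of the fluorescence
#' amplitudes on that fixed Boltzmann shape and mapped to 0-1. With
#' voltage-independent post-gating transitions the normalized F-V then
#' superimposes exactly on the normalized Q-V.
#'
#' @param bfit a [fit_boltzmann()] result from the same cell's Q-V.
#' @param voltage F-V voltages, mV.
#' @param famp -dF/F0 amplitudes at each voltage.
#' @return list with `normalized`, `Fmin`, `Fmax`.
#' @export
normalize_fv_with_qv <- function(bfit, voltage, famp) {
  Vt <- thermal_voltage(bfit$temperature_C)
  b <- 1 / (1 + exp(-bfit$z * (voltage - bfit$V_half) / Vt))
  cf <- stats::lm.fit(cbind(1, b), famp)$coefficients
  list(normalized = (famp - cf[1]) / cf[2],
       Fmin = unname(cf[1]), Fmax = unname(cf[1] + cf[2]))
}

# Analyse one sweep: baseline-corrected gating charge + decay kinetics and
# -dF/F0 amplitude, lag and kinetics.
.analyze_sweep <- function(time, gating, fluor, protocol, step,
                           n_gating_components = 2) {
  onset <- protocol$step_onset
  pend <- onset + protocol$step_duration
  bw <- c(onset + 0.8 * protocol$step_duration, pend)  # current fully decayed
  g <- subtract_sloped_baseline(time, gating, bw)
  charge <- integrate_charge(time, g, c(onset, pend))
  gfit <- tryCatch(
    fit_gating_decay(time, g, c(onset, pend), n_components = n_gating_components),
    error = function(e) NULL)
  dff <- compute_dff(time, fluor, c(0, onset))
  amp_sel <- time >= onset + 0.9 * protocol$step_duration & time < pend
  famp <- mean(dff[amp_sel])
  lag <- tryCatch(extract_lag(time, dff, onset, window = c(onset, pend)),
                  error = function(e) NULL)
  fstart <- if (!is.null(lag) && isTRUE(lag$defined) && lag$crossing > onset &&
                lag$crossing < pend - 10) lag$crossing else onset
  ffit <- tryCatch(fit_fluor_kinetics(time, dff, c(fstart, pend)),
                   error = function(e) NULL)
  list(step = step, charge = charge, gating_fit = gfit, famp = famp,
       lag = lag, fluor_fit = ffit, dff = dff, corrected_gating = g)
}

#' Build Q-V, F-V, tau-V and lag-V curves from a recording
#'
#' Runs the full per-sweep analysis (sloped-baseline subtraction, charge
#' integration, double-exponential gating kinetics, -dF/F0, abscissa-crossing
#' lag, fluorescence kinetics with the single-exponential refit rule) over a
#' sweep family and assembles the voltage-indexed curves. Q-V normalization
#' uses Boltzmann limits for saturating families or a same-cell total-charge
#' reference for non-saturating (depolarized-holding) families; the F-V is
#' normalized with the scaling factors of the same cell's Q-V.
#'
#' Gating kinetics are only reported at steps carrying at least
#' `min_charge_frac` of the maximal charge, and fluorescence kinetics/lag at
#' steps whose amplitude reaches `min_response_frac` of the maximal response;
#' below that the fits measure noise, not kinetics. Missing steps are gaps.
#'
#' @param recording a [simulate_macroscopic_recording()] result.
#' @param qv_normalization `"boltzmann"` or `"total-charge"`.
#' @param reference_total_charge same-cell reference charge, required for
#'   `"total-charge"` normalization.
#' @param min_charge_frac,min_response_frac reporting thresholds.
#' @return object of class `vcf_curves`: data.frames `qv`, `fv`,
#'   `tau_gating`, `tau_fluor`, `lag`, plus `boltzmann` (fit or NULL) and
#'   `total_charge` (charge moved at the most saturating step).
#' @export
build_curves <- function(recording,
                         qv_normalization = c("boltzmann", "total-charge"),
                         reference_total_charge = NULL,
                         min_charge_frac = 0.05, min_response_frac = 0.05) {
  qv_normalization <- match.arg(qv_normalization)
  pr <- recording$protocol
  steps <- pr$step_levels
  res <- lapply(steps, function(s) {
    sw <- recording$sweeps[[as.character(s)]]
    .analyze_sweep(sw$time, sw$gating, sw$fluorescence, pr, s)
  })
  ord <- order(steps)
  steps <- steps[ord]; res <- res[ord]
  charge <- vapply(res, `[[`, numeric(1), "charge")
  famp <- vapply(res, `[[`, numeric(1), "famp")
  # depolarized-holding families move charge in the negative direction;
  # report magnitude moved relative to holding
  sgn <- if (pr$holding > mean(range(steps))) -1 else 1
  qv <- data.frame(voltage = steps, charge = sgn * charge)
  bfit <- NULL
  if (qv_normalization == "boltzmann") {
    bfit <- fit_boltzmann(qv$voltage, qv$charge,
                          temperature_C = recording$temperature_C %||% 19)
    qv$norm <- bfit$normalized
  } else {
    if (is.null(reference_total_charge)) {
      stop("total-charge normalization needs reference_total_charge")
    }
    qv$norm <- normalize_qv_nonsaturating(qv$voltage, qv$charge,
                                          reference_total_charge)$normalized
  }
  fv <- data.frame(voltage = steps, dff = famp)
  fv$norm <- if (!is.null(bfit)) {
    normalize_fv_with_qv(bfit, fv$voltage, fv$dff)$normalized
  } else if (!is.null(reference_total_charge) && max(abs(famp)) > 0) {
    famp / max(abs(famp))
  } else NA_real_
  keep_g <- abs(qv$charge) >= min_charge_frac * max(abs(qv$charge)) &
    !vapply(res, function(r) is.null(r$gating_fit), logical(1))
  tau_gating <- data.frame(
    voltage = steps[keep_g],
    tau_w = vapply(res[keep_g], function(r) r$gating_fit$tau_w, numeric(1))
  )
  keep_f <- abs(famp) >= min_response_frac * max(abs(famp)) &
    !vapply(res, function(r) is.null(r$fluor_fit), logical(1))
  tau_fluor <- data.frame(
    voltage = steps[keep_f],
    tau1 = vapply(res[keep_f], function(r) r$fluor_fit$tau1, numeric(1)),
    frac_fast = vapply(res[keep_f], function(r) r$fluor_fit$frac_fast, numeric(1)),
    refit = vapply(res[keep_f], function(r) r$fluor_fit$refit, logical(1))
  )
  keep_l <- keep_f & vapply(res, function(r) {
    !is.null(r$lag) && isTRUE(r$lag$defined)
  }, logical(1))
  lag <- data.frame(
    voltage = steps[keep_l],
    lag = vapply(res[keep_l], function(r) r$lag$lag, numeric(1)),
    crossing = vapply(res[keep_l], function(r) r$lag$crossing, numeric(1))
  )
  isat <- if (sgn > 0) which.max(steps) else which.min(steps)
  structure(list(
    qv = qv, fv = fv, tau_gating = tau_gating, tau_fluor = tau_fluor,
    lag = lag, boltzmann = bfit, total_charge = abs(charge[isat]),
    holding = pr$holding, sweep_results = res
  ), class = "vcf_curves")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Export the curve tables of a `vcf_curves` object as CSV files
#'
#' Writes `qv.csv`, `fv.csv`, `tau_gating.csv`, `tau_fluor.csv`, `lag.csv`
#' into `dir`.
#'
#' @param curves a [build_curves()] result.
#' @param dir output directory (created if needed).
#' @return invisibly, the written paths.
#' @export
write_curves <- function(curves, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  out <- character(0)
  for (nm in c("qv", "fv", "tau_gating", "tau_fluor", "lag")) {
    p <- file.path(dir, paste0(nm, ".csv"))
    utils::write.csv(curves[[nm]], p, row.names = FALSE)
    out <- c(out, p)
  }
  invisible(out)
}
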