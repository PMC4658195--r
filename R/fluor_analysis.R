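#' Fractional fluorescence change, dimming-positive
#'
#' Computes `-(F(t) - F0)/F0` with `F0` the mean over a pre-pulse baseline
#' window, so that the depolarization-induced dimming of ArcLight appears as
#' a positive deflection throughout the pipeline.
#'
#' @param time time vector, ms.
#' @param trace raw fluorescence.
#' @param baseline_window `c(start, end)` ms, preceding the step onset.
#' @return -dF/F0 trace.
#' @export
compute_dff <- function(time, trace, baseline_window) {
  sel <- time >= baseline_window[1] & time < baseline_window[2]
  if (!any(sel)) stop("empty baseline window")
  F0 <- mean(trace[sel])
  if (F0 <= 0) stop("non-positive baseline fluorescence F0")
  -(trace - F0) / F0
}

#' Zero-phase Gaussian low-pass filter
#'
#' Symmetric Gaussian FIR kernel with unit DC gain; being zero-phase it
#' introduces no lag, so filtering cannot bias lag estimates. The cutoff is
#' the -3 dB frequency. Edges are handled by replicate padding.
#'
#' @param trace input trace.
#' @param cutoff_hz -3 dB cutoff, Hz (must be below Nyquist).
#' @param sample_interval_ms sampling interval, ms.
#' @return filtered trace, same length.
#' @export
lowpass_filter <- function(trace, cutoff_hz, sample_interval_ms) {
  nyq <- 1000 / (2 * sample_interval_ms)
  if (cutoff_hz >= nyq) stop(sprintf("cutoff %g Hz >= Nyquist %g Hz", cutoff_hz, nyq))
  sigma_ms <- sqrt(log(2)) / (2 * pi * cutoff_hz) * 1000
  sigma_samp <- sigma_ms / sample_interval_ms
  half <- max(1L, ceiling(4 * sigma_samp))
  k <- exp(-0.5 * ((-half:half) / sigma_samp)^2)
  k <- k / sum(k)
  padded <- c(rep(trace[1], half), trace, rep(trace[length(trace)], half))
  as.numeric(stats::filter(padded, k, sides = 2))[(half + 1):(half + length(trace))]
}

#' Drift-baseline subtraction (linear or single-exponential)
#'
#' Fits a drift model to the quiescent regions of a trace (pre-pulse and,
#' where available, post-recovery) and removes it everywhere. If the
#' exponential fit does not converge the function falls back to the linear
#' model with a warning.
#'
#' @param time time vector, ms.
#' @param trace input trace.
#' @param regions list of `c(start, end)` windows (ms) that contain no
#'   response, used to fit the drift.
#' @param mode `"linear"` or `"single_exponential"`.
#' @return corrected trace (quiescent-region mean approximately zero).
#' @export
subtract_baseline <- function(time, trace, regions,
                              mode = c("linear", "single_exponential")) {
  mode <- match.arg(mode)
  sel <- Reduce(`|`, lapply(regions, function(w) time >= w[1] & time < w[2]))
  if (sum(sel) < 4) stop("baseline regions contain too few samples")
  tb <- time[sel]; yb <- trace[sel]
  if (mode == "linear") {
    cf <- stats::lm.fit(cbind(1, tb), yb)$coefficients
    return(trace - (cf[1] + cf[2] * time))
  }
  fit <- tryCatch({
    tg <- max(diff(range(time)) / 2, 1)
    df <- data.frame(t = tb, y = yb)
    minpack.lm::nlsLM(y ~ a + b * exp(-t / tau), data = df,
                      start = list(a = mean(yb), b = yb[1] - mean(yb),
                                   tau = tg),
                      lower = c(-Inf, -Inf, 1e-3),
                      control = minpack.lm::nls.lm.control(maxiter = 200))
  }, error = function(e) NULL)
  if (is.null(fit)) {
    warning("single-exponential baseline fit failed; falling back to linear")
    return(subtract_baseline(time, trace, regions, "linear"))
  }
  cf <- stats::coef(fit)
  trace - (cf[["a"]] + cf[["b"]] * exp(-time / cf[["tau"]]))
}

#' Double-exponential kinetics of a fluorescence response with refit rule
#'
#' Fits two exponentials to a -dF/F0 trace over the given window; if the
#' second component is not meaningful — amplitude fraction below
#' `refit_amp_frac` or time constants within a factor `refit_tau_ratio` of
#' each other — the trace is refit with a single exponential and the refit
#' flag is set. Kinetics are reported as `tau1`, the faster component, with
#' its fractional amplitude.
#'
#' @param time time vector, ms.
#' @param dff dimming-positive fractional fluorescence trace.
#' @param window `c(start, end)` ms; should begin at the response onset (or
#'   at the extracted lag crossing, see [extract_lag()]).
#' @param refit_amp_frac amplitude-fraction threshold below which the second
#'   component is dropped (default 0.05).
#' @param refit_tau_ratio minimum tau2/tau1 separation (default 1.5).
#' @return object of class `fluor_kinetics_fit`: an `exp_decay_fit` plus
#'   `tau1`, `frac_fast`, `refit` flag and the fit window.
#' @export
fit_fluor_kinetics <- function(time, dff, window, refit_amp_frac = 0.05,
                               refit_tau_ratio = 1.5) {
  sel <- time >= window[1] & time < window[2]
  if (sum(sel) < 8) stop("kinetics window too short")
  f2 <- fit_exp_decay(time[sel], dff[sel], n_components = 2)
  amp <- abs(f2$components$amplitude)
  frac2 <- amp[2] / sum(amp)
  tau_ratio <- f2$components$tau[2] / f2$components$tau[1]
  refit <- !is.finite(frac2) || frac2 < refit_amp_frac ||
    tau_ratio < refit_tau_ratio
  fit <- if (refit) fit_exp_decay(time[sel], dff[sel], n_components = 1) else f2
  amp <- abs(fit$components$amplitude)
  # reported kinetics: the faster-and-larger component; when the amplitudes
  # disagree with the speed ordering the dominant-amplitude one is reported,
  # with near-equal amplitudes (within 10%) resolved toward the faster
  idom <- which.max(amp)
  if (nrow(fit$components) == 2 && diff(range(amp)) < 0.1 * sum(amp)) {
    idom <- 1L
  }
  fit$tau1 <- fit$components$tau[idom]
  fit$frac_fast <- amp[1] / sum(amp)
  fit$refit <- refit
  fit$window <- window
  class(fit) <- c("fluor_kinetics_fit", class(fit))
  fit
}

#' Fluorescence lag by abscissa crossing of an exponential fit
#'
#' The onset delay of the fluorescence response is measured where an
#' exponential fitted to the response crosses the baseline (the abscissa):
#' the fit is extrapolated backwards from the response and the first crossing
#' after (or nearest) the voltage onset is found; lag = crossing - onset.
#' A slightly negative lag is reported as-is (fit noise); a fit that never
#' crosses zero yields `NA` with `defined = FALSE`.
#'
#' If no `fit` is supplied, a single exponential is fitted from the departure
#' point (the first time after onset at which the response exceeds
#' `departure_frac` of its final amplitude) to `window[2]`.
#'
#' @param time time vector, ms.
#' @param dff dimming-positive -dF/F0 trace (baseline near zero).
#' @param onset voltage-step onset time, ms.
#' @param fit optional [fit_fluor_kinetics()] result to use for the crossing.
#' @param window `c(start, end)` ms containing the response (default: onset
#'   to end of trace).
#' @param departure_frac departure threshold as a fraction of the final
#'   response amplitude (default 0.05).
#' @return list of class `lag_result`: `crossing` (ms), `onset` (ms),
#'   `lag` (ms), `defined`, and the fit used.
#' @export
extract_lag <- function(time, dff, onset, fit = NULL,
                        window = c(onset, max(time)), departure_frac = 0.05) {
  if (is.null(fit)) {
    sel <- which(time >= window[1] & time < window[2])
    if (length(sel) < 8) stop("lag window too short")
    yend <- mean(dff[utils::tail(sel, max(3, round(length(sel) * 0.05)))])
    if (!is.finite(yend) || abs(yend) < .Machine$double.eps * 100) {
      return(structure(list(crossing = NA_real_, onset = onset,
                            lag = NA_real_, defined = FALSE, fit = NULL),
                       class = "lag_result"))
    }
    dep <- sel[which(sign(yend) * dff[sel] >= departure_frac * abs(yend))[1]]
    if (is.na(dep)) dep <- sel[1]
    ksel <- which(time >= time[dep] & time < window[2])
    fit <- fit_exp_decay(time[ksel], dff[ksel], n_components = 1)
    fit$window <- c(time[dep], window[2])
  }
  f <- fit$predict
  lo <- onset - 0.5 * diff(range(time))
  hi <- fit$window[2]
  grid <- seq(lo, hi, length.out = 2048)
  vals <- f(grid)
  sgn <- sign(vals)
  flips <- which(sgn[-1] * sgn[-length(sgn)] <= 0 & sgn[-1] != 0)
  crossing <- NA_real_
  if (length(flips)) {
    # crossing closest to (preferring after) the onset
    cand <- vapply(flips, function(i) {
      stats::uniroot(f, c(grid[i], grid[i + 1]), tol = 1e-10)$root
    }, numeric(1))
    after <- cand[cand >= onset - 1e-9]
    crossing <- if (length(after)) min(after) else max(cand)
  }
  structure(list(crossing = crossing, onset = onset,
                 lag = crossing - onset, defined = is.finite(crossing),
                 fit = fit),
            class = "lag_result")
}

#' @export
print.lag_result <- function(x, ...) {
  cat(sprintf("<lag_result: crossing = %.3f ms, onset = %.3f ms, lag = %.3f ms>\n",
              x$crossing, x$onset, x$lag))
  invisible(x)
}
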