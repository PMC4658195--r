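#' Sloped-baseline (leak) subtraction
#'
#' Fits a straight line to the trace over a quiescent window (by default the
#' final 20% of the window supplied should contain no gating current) and
#' subtracts it from the entire trace, removing linear leak and offset.
#'
#' @param time time vector, ms.
#' @param trace current trace.
#' @param baseline_window `c(start, end)` in ms, half-open, with at least 10
#'   samples inside.
#' @return corrected trace.
#' @export
subtract_sloped_baseline <- function(time, trace, baseline_window) {
  sel <- time >= baseline_window[1] & time < baseline_window[2]
  if (sum(sel) < 10) stop("baseline window must contain at least 10 samples")
  tw <- time[sel]
  if (stats::var(tw) == 0) stop("degenerate baseline window (no time spread)")
  fit <- stats::lm.fit(cbind(1, tw), trace[sel])
  trace - (fit$coefficients[1] + fit$coefficients[2] * time)
}

#' Integrated gating charge over a window
#'
#' Trapezoidal integral of a baseline-subtracted gating-current trace over
#' the half-open window `[start, end)` — excluding the right endpoint
#' matters when the window ends exactly on a voltage edge, where the sample
#' already belongs to the next command level.
#'
#' @inheritParams subtract_sloped_baseline
#' @param window `c(start, end)` in ms, half-open.
#' @return charge (current units x ms).
#' @export
integrate_charge <- function(time, trace, window) {
  sel <- time >= window[1] & time < window[2]
  if (sum(sel) < 2) stop("integration window lies outside the trace")
  tt <- time[sel]; yy <- trace[sel]
  sum(diff(tt) * (head(yy, -1) + tail(yy, -1)) / 2)
}

#' Boltzmann fit and normalization of a Q-V curve
#'
#' Fits `Q(V) = Qmin + (Qmax - Qmin) / (1 + exp(-z (V - Vhalf)/Vt))` and
#' rescales the curve so the fitted limits map to 0 and 1. The fitted shape
#' parameters (`Vhalf`, `z`) are retained so the same cell's F-V curve can be
#' normalized with the scaling factors derived from its Q-V.
#'
#' @param voltage voltages, mV (strictly increasing).
#' @param charge charge moved at each voltage.
#' @param temperature_C temperature defining Vt = RT/F (default 19).
#' @return object of class `boltzmann_fit`: `V_half` (mV), `z` (e0), `Qmin`,
#'   `Qmax`, `normalized` (curve mapped to the 0-1 limits), plus the input
#'   curve.
#' @export
fit_boltzmann <- function(voltage, charge, temperature_C = 19) {
  stopifnot(length(voltage) == length(charge), length(voltage) >= 5,
            all(diff(voltage) > 0))
  Vt <- thermal_voltage(temperature_C)
  qmin0 <- min(charge); qmax0 <- max(charge)
  mid <- (qmin0 + qmax0) / 2
  vh0 <- voltage[which.min(abs(charge - mid))]
  # slope guess from the central rise
  rng <- qmax0 - qmin0
  inner <- charge > qmin0 + 0.25 * rng & charge < qmin0 + 0.75 * rng
  z0 <- if (sum(inner) >= 2) {
    sl <- stats::coef(stats::lm(charge[inner] ~ voltage[inner]))[2]
    max(min(4 * sl * Vt / rng, 6), 0.2)
  } else 1
  df <- data.frame(V = voltage, Q = charge)
  # variable projection: for trial (Vh, z) the limits are linear
  vp_rss <- function(p) {
    b <- 1 / (1 + exp(-exp(p[2]) * (voltage - p[1]) / Vt))
    f <- tryCatch(stats::lm.fit(cbind(1, b), charge), error = function(e) NULL)
    if (is.null(f)) Inf else sum(f$residuals^2)
  }
  vp <- NULL
  for (zs in unique(c(z0, 0.5, 1, 2))) {
    o <- stats::optim(c(vh0, log(zs)), vp_rss, method = "Nelder-Mead",
                      control = list(maxit = 500, reltol = 1e-12))
    if (is.null(vp) || o$value < vp$value) vp <- o
  }
  b <- 1 / (1 + exp(-exp(vp$par[2]) * (voltage - vp$par[1]) / Vt))
  lin <- stats::lm.fit(cbind(1, b), charge)$coefficients
  start <- list(Qmin = unname(lin[1]), Qmax = unname(lin[1] + lin[2]),
                Vh = vp$par[1], z = exp(vp$par[2]))
  # bounded Gauss-Newton polish from the projected optimum (port algorithm:
  # re-entrant, so Boltzmann fits may run inside outer least-squares loops)
  fit <- tryCatch(
    stats::nls(Q ~ Qmin + (Qmax - Qmin) / (1 + exp(-z * (V - Vh) / Vt)),
               data = df, start = start, algorithm = "port",
               lower = c(-Inf, -Inf, min(voltage) - 300, 1e-3),
               upper = c(Inf, Inf, max(voltage) + 300, 10),
               control = stats::nls.control(maxiter = 200, warnOnly = TRUE)),
    error = function(e) NULL)
  cf <- if (!is.null(fit)) stats::coef(fit) else unlist(start)
  if (!is.finite(cf[["Qmin"]]) || !is.finite(cf[["Qmax"]])) {
    stop(sprintf(paste0("Boltzmann fit failed; starting values were ",
                        "Qmin=%.3g Qmax=%.3g Vh=%.3g z=%.3g"),
                 start$Qmin, start$Qmax, start$Vh, start$z))
  }
  if (cf[["Qmax"]] < cf[["Qmin"]]) {   # keep asymptotes ordered
    cf[c("Qmin", "Qmax")] <- cf[c("Qmax", "Qmin")]
  }
  structure(list(
    V_half = unname(cf[["Vh"]]), z = unname(cf[["z"]]),
    Qmin = unname(cf[["Qmin"]]), Qmax = unname(cf[["Qmax"]]),
    temperature_C = temperature_C,
    voltage = voltage, charge = charge,
    normalized = (charge - cf[["Qmin"]]) / (cf[["Qmax"]] - cf[["Qmin"]]),
    vcov = if (!is.null(fit)) tryCatch(stats::vcov(fit),
                                       error = function(e) NULL) else NULL
  ), class = "boltzmann_fit")
}

#' @export
print.boltzmann_fit <- function(x, ...) {
  cat(sprintf("<boltzmann_fit: V1/2 = %.2f mV, z = %.3f e0>\n", x$V_half, x$z))
  invisible(x)
}

#' Normalize a non-saturating Q-V by a same-cell total-charge reference
#'
#' For families recorded from a depolarized holding potential the Q-V does
#' not saturate at the hyperpolarized end, so Boltzmann limits are not
#' defined; instead the curve is divided by the total gating charge moved in
#' the same cell during a saturating depolarizing family. The factor is
#' returned so the matching F-V can be normalized identically.
#'
#' @param voltage voltages, mV.
#' @param charge charge values.
#' @param reference_total_charge total charge from the saturating family of
#'   the same cell (> 0).
#' @return list with `voltage`, `normalized`, `factor`.
#' @export
normalize_qv_nonsaturating <- function(voltage, charge, reference_total_charge) {
  stopifnot(reference_total_charge > 0)
  list(voltage = voltage, normalized = charge / reference_total_charge,
       factor = reference_total_charge)
}

#' Double-exponential fit to the decay phase of a gating current
#'
#' The decay window starts one sample after the time of maximum |current|
#' inside the supplied window (avoiding the clamp-settling rising phase) and
#' the weighted time constant is the amplitude-weighted mean of the two
#' fitted time constants.
#'
#' @inheritParams subtract_sloped_baseline
#' @param window `c(start, end)` ms within which the decay lies; the fit
#'   starts just after the |current| peak inside this window.
#' @param n_components number of exponential components (default 2).
#' @return an `exp_decay_fit` (see [fit_exp_decay()]) with the decay window
#'   start stored in `t0`.
#' @export
fit_gating_decay <- function(time, trace, window, n_components = 2) {
  sel <- which(time >= window[1] & time < window[2])
  if (length(sel) < 10) stop("decay window too short")
  ipk <- sel[which.max(abs(trace[sel]))]
  start <- ipk + 1L
  if (start > max(sel) - 6L) stop("no decay phase after the current peak")
  idx <- start:max(sel)
  fit_exp_decay(time[idx], trace[idx], n_components = n_components)
}
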