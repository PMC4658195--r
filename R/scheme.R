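#' Thermal voltage RT/F
#'
#' @param temperature_C temperature in degrees Celsius.
#' @return RT/F in millivolts.
#' @export
thermal_voltage <- function(temperature_C) {
  1000 * 8.314462618 * (temperature_C + 273.15) / 96485.33212
}

#' Construct a linear-chain voltage-dependent kinetic scheme
#'
#' States form a linear chain `S1 - S2 - ... - Sn` (n = 3 or 4). Transition i
#' (connecting state i and state i+1) has forward rate at 0 mV `k_f0[i]`,
#' backward rate `k_b0[i]` (both 1/ms), gating charge `z[i]` (elementary
#' charges) and charge-symmetry factor `delta[i]` in [0, 1]. Voltage dependence
#' follows a single-barrier (Eyring-type) law,
#' `kf(V) = k_f0 * exp(z * delta * V / Vt)` and
#' `kb(V) = k_b0 * exp(-z * (1 - delta) * V / Vt)` with `Vt = RT/F`.
#' By convention the first transition carries the gating charge and the last
#' transition carries the fluorescence change (the final state differs in
#' brightness).
#'
#' @param k_f0 forward rates at 0 mV, length n-1, 1/ms.
#' @param k_b0 backward rates at 0 mV, length n-1, 1/ms.
#' @param z gating charge per transition, length n-1, elementary charges.
#' @param delta charge-symmetry factors in [0, 1], length n-1 (recycled).
#' @param brightness per-state relative emission, length n, finite and >= 0.
#' @param temperature_C temperature in degrees Celsius (default 19).
#' @param name optional scheme label.
#' @return object of class `kinetic_scheme`.
#' @export
kinetic_scheme <- function(k_f0, k_b0, z, delta = 0.5, brightness,
                           temperature_C = 19, name = "scheme") {
  nt <- length(k_f0)
  n <- nt + 1L
  if (!(n %in% c(2L, 3L, 4L))) {
    stop("kinetic_scheme supports 2, 3 or 4 states (1-3 transitions)")
  }
  delta <- rep_len(delta, nt)
  stopifnot(length(k_b0) == nt, length(z) == nt, length(brightness) == n)
  if (any(!is.finite(k_f0)) || any(k_f0 <= 0) ||
      any(!is.finite(k_b0)) || any(k_b0 <= 0)) {
    stop("all rates must be finite and > 0")
  }
  if (any(delta < 0 | delta > 1)) stop("delta must lie in [0, 1]")
  if (any(!is.finite(brightness)) || any(brightness < 0)) {
    stop("brightness must be finite and >= 0")
  }
  structure(list(
    n_states = n, k_f0 = as.numeric(k_f0), k_b0 = as.numeric(k_b0),
    z = as.numeric(z), delta = delta,
    brightness = as.numeric(brightness),
    temperature_C = temperature_C,
    Vt = thermal_voltage(temperature_C),
    name = name
  ), class = "kinetic_scheme")
}

#' @export
print.kinetic_scheme <- function(x, ...) {
  cat(sprintf("<kinetic_scheme '%s': %d states, %.1f C (Vt = %.2f mV)>\n",
              x$name, x$n_states, x$temperature_C, x$Vt))
  tr <- data.frame(
    transition = seq_len(x$n_states - 1L),
    k_f0 = x$k_f0, k_b0 = x$k_b0, z = x$z, delta = x$delta
  )
  print(tr, row.names = FALSE)
  cat("brightness:", paste(signif(x$brightness, 4), collapse = ", "), "\n")
  invisible(x)
}

#' Voltage-dependent transition rates
#'
#' @param scheme a [kinetic_scheme()].
#' @param V membrane potential, mV.
#' @return list with vectors `kf` and `kb` (1/ms, one entry per transition).
#' @export
transition_rates <- function(scheme, V) {
  stopifnot(is.finite(V))
  kf <- scheme$k_f0 * exp(scheme$z * scheme$delta * V / scheme$Vt)
  kb <- scheme$k_b0 * exp(-scheme$z * (1 - scheme$delta) * V / scheme$Vt)
  bad <- which(!is.finite(kf) | !is.finite(kb))
  if (length(bad)) {
    stop(sprintf("non-finite rate at V = %g mV for transition %s (overflow)",
                 V, paste(bad, collapse = ", ")))
  }
  list(kf = kf, kb = kb)
}

#' Generator matrix of the chain at a fixed voltage
#'
#' Returns the n x n infinitesimal generator Q (units 1/ms) for row-vector
#' occupancy dynamics dp/dt = p Q: off-diagonal entries are non-negative and
#' every row sums to zero.
#'
#' @inheritParams transition_rates
#' @return n x n numeric matrix.
#' @export
rate_matrix <- function(scheme, V) {
  r <- transition_rates(scheme, V)
  n <- scheme$n_states
  Q <- matrix(0, n, n)
  for (i in seq_len(n - 1L)) {
    Q[i, i + 1L] <- r$kf[i]
    Q[i + 1L, i] <- r$kb[i]
  }
  diag(Q) <- -rowSums(Q)
  Q
}

#' Equilibrium occupancy of the chain at a fixed voltage
#'
#' Computed from the equilibrium constants `K_i(V) = kf_i(V)/kb_i(V)` by
#' detailed balance along the chain; always sums to one.
#'
#' @inheritParams transition_rates
#' @return occupancy vector of length `n_states`.
#' @export
steady_state <- function(scheme, V) {
  r <- transition_rates(scheme, V)
  logw <- c(0, cumsum(log(r$kf) - log(r$kb)))
  logw <- logw - max(logw)   # overflow guard
  w <- exp(logw)
  w / sum(w)
}

#' Steady-state fluorescence at a fixed voltage
#'
#' @inheritParams transition_rates
#' @return relative emission (occupancy-weighted brightness).
#' @export
steady_state_fluorescence <- function(scheme, V) {
  sum(steady_state(scheme, V) * scheme$brightness)
}

#' Scale the rates of one transition
#'
#' Used to model gating-acceleration mutants: e.g. scaling transition 1 of the
#' ArcLight scheme forward x10 and backward x20 yields the ArcLightning scheme.
#'
#' @param scheme a [kinetic_scheme()].
#' @param transition transition index.
#' @param forward,backward multiplicative factors for the 0 mV rates.
#' @param name label for the derived scheme.
#' @return a new `kinetic_scheme`.
#' @export
scale_transition <- function(scheme, transition, forward = 1, backward = forward,
                             name = scheme$name) {
  stopifnot(transition >= 1, transition <= scheme$n_states - 1L)
  scheme$k_f0[transition] <- scheme$k_f0[transition] * forward
  scheme$k_b0[transition] <- scheme$k_b0[transition] * backward
  scheme$name <- name
  scheme
}

#' Shift the voltage dependence of one transition
#'
#' Multiplies the 0 mV rates so that all voltage-dependent quantities of that
#' transition are translated by `dV` along the voltage axis (a V1/2 shift),
#' leaving the peak relaxation rate unchanged.
#'
#' @param scheme a [kinetic_scheme()].
#' @param transition transition index.
#' @param dV shift in mV (positive = rightward shift of the Q-V).
#' @param name label for the derived scheme.
#' @return a new `kinetic_scheme`.
#' @export
shift_transition <- function(scheme, transition, dV, name = scheme$name) {
  z <- scheme$z[transition]
  d <- scheme$delta[transition]
  scheme$k_f0[transition] <- scheme$k_f0[transition] * exp(-z * d * dV / scheme$Vt)
  scheme$k_b0[transition] <- scheme$k_b0[transition] * exp(z * (1 - d) * dV / scheme$Vt)
  scheme$name <- name
  scheme
}

#' Serialize a scheme to JSON
#' @param scheme a [kinetic_scheme()].
#' @param path file to write.
#' @export
write_scheme <- function(scheme, path) {
  x <- unclass(scheme)
  x$Vt <- NULL
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a scheme from JSON
#' @param path file written by [write_scheme()].
#' @return a `kinetic_scheme`.
#' @export
read_scheme <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  kinetic_scheme(x$k_f0, x$k_b0, x$z, x$delta, x$brightness,
                 x$temperature_C, x$name)
}
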