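# Matrix exponential by scaling-and-squaring (Taylor); fallback only, the
# chain generators used here are diagonalizable in practice.
.expm_ss <- function(A, nterm = 16L) {
  nrm <- max(rowSums(abs(A)))
  s <- max(0L, ceiling(log2(max(nrm, .Machine$double.eps))))
  As <- A / 2^s
  E <- diag(nrow(A))
  term <- diag(nrow(A))
  for (k in seq_len(nterm)) {
    term <- term %*% As / k
    E <- E + term
  }
  for (k in seq_len(s)) E <- E %*% E
  E
}

# Occupancy rows p0 exp(Q * t) for all t >= 0 in `trel`, via eigendecomposition.
.propagate_segment <- function(p0, Q, trel) {
  eg <- tryCatch(eigen(Q), error = function(e) NULL)
  ok <- !is.null(eg)
  if (ok) {
    Rinv <- tryCatch(solve(eg$vectors), error = function(e) NULL)
    ok <- !is.null(Rinv)
  }
  if (ok) {
    c0 <- as.vector(p0 %*% eg$vectors)
    E <- exp(outer(trel, eg$values))
    P <- (E * matrix(c0, length(trel), length(c0), byrow = TRUE)) %*% Rinv
    if (is.complex(P)) {
      if (max(abs(Im(P))) > 1e-8) ok <- FALSE else P <- Re(P)
    }
    if (ok && all(is.finite(P))) return(P)
  }
  # defective or ill-conditioned eigensystem: step with expm
  P <- matrix(0, length(trel), length(p0))
  ord <- order(trel)
  p <- p0
  tprev <- 0
  for (j in ord) {
    dt <- trel[j] - tprev
    if (dt > 0) p <- p %*% .expm_ss(Q * dt)
    P[j, ] <- p
    tprev <- trel[j]
  }
  P
}

#' Deterministic occupancy trajectory under a step protocol
#'
#' Solves dp/dt = p Q(V(t)) for a piecewise-constant command voltage with an
#' exact propagator (eigendecomposition of the generator) on each segment, so
#' there is no ODE stepping error. The trajectory starts from equilibrium at
#' the first segment's voltage unless an explicit initial occupancy is given.
#'
#' @param scheme a [kinetic_scheme()].
#' @param protocol a [voltage_protocol()].
#' @param step step level selecting the sweep (mV).
#' @param initial `"holding"` (equilibrate at the first segment's voltage) or
#'   an occupancy vector summing to one.
#' @return object of class `state_trajectory`: list with `time` (ms),
#'   `occupancy` (time x state matrix), `voltage` (mV) and `step`.
#' @export
propagate_occupancy <- function(scheme, protocol, step = protocol$step_levels[1],
                                initial = "holding") {
  seg <- protocol_segments(protocol, step)
  times <- protocol_times(protocol)
  n <- scheme$n_states
  if (identical(initial, "holding")) {
    p <- steady_state(scheme, seg$V[1])
  } else {
    stopifnot(length(initial) == n, abs(sum(initial) - 1) < 1e-8)
    p <- as.numeric(initial)
  }
  occ <- matrix(NA_real_, length(times), n)
  for (k in seq_len(nrow(seg))) {
    Q <- rate_matrix(scheme, seg$V[k])
    last <- k == nrow(seg)
    in_seg <- times >= seg$t0[k] & (if (last) times <= seg$t1[k] else times < seg$t1[k])
    if (any(in_seg)) {
      occ[in_seg, ] <- .propagate_segment(p, Q, times[in_seg] - seg$t0[k])
    }
    if (!last) {
      p <- as.vector(.propagate_segment(p, Q, seg$t1[k] - seg$t0[k]))
    }
    if (any(!is.finite(occ[in_seg, ])) || any(!is.finite(p))) {
      stop(sprintf("occupancy propagation failed in segment %d (V = %g mV)",
                   k, seg$V[k]))
    }
  }
  structure(list(
    time = times, occupancy = occ,
    voltage = voltage_trace(protocol, step, times),
    step = step, scheme_name = scheme$name
  ), class = "state_trajectory")
}

#' Gating current of a trajectory
#'
#' The per-molecule gating current is the charge-weighted net forward flux
#' across each transition, `sum_i z_i (p_i(t) kf_i(V) - p_{i+1}(t) kb_i(V))`,
#' in units of elementary charges per ms; `n_molecules` scales it to a
#' macroscopic current. Its time integral over a step from equilibrium equals
#' the total gating charge moved.
#'
#' @param trajectory a [propagate_occupancy()] result from the same scheme.
#' @param scheme the generating [kinetic_scheme()].
#' @param n_molecules number of sensor molecules.
#' @return current trace (e0/ms), same length as `trajectory$time`.
#' @export
gating_current <- function(trajectory, scheme, n_molecules = 1) {
  occ <- trajectory$occupancy
  if (ncol(occ) != scheme$n_states) {
    stop("trajectory and scheme have different numbers of states")
  }
  V <- trajectory$voltage
  I <- numeric(nrow(occ))
  for (i in seq_len(scheme$n_states - 1L)) {
    if (scheme$z[i] == 0) next
    kf <- scheme$k_f0[i] * exp(scheme$z[i] * scheme$delta[i] * V / scheme$Vt)
    kb <- scheme$k_b0[i] * exp(-scheme$z[i] * (1 - scheme$delta[i]) * V / scheme$Vt)
    I <- I + scheme$z[i] * (occ[, i] * kf - occ[, i + 1L] * kb)
  }
  n_molecules * I
}

#' Fluorescence of a trajectory
#'
#' Occupancy-weighted brightness, `F(t) = sum_s p_s(t) b_s`, in relative
#' units. For the reference ArcLight parameterization the final (post-gating)
#' state is dim, so depolarization from a negative holding potential lowers F.
#'
#' @inheritParams gating_current
#' @return relative fluorescence trace.
#' @export
fluorescence_signal <- function(trajectory, scheme) {
  if (ncol(trajectory$occupancy) != scheme$n_states) {
    stop("trajectory and scheme have different numbers of states")
  }
  as.vector(trajectory$occupancy %*% scheme$brightness)
}
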