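# Exit rates and forward-jump probabilities per state at fixed V.
.jump_table <- function(scheme, V) {
  r <- transition_rates(scheme, V)
  n <- scheme$n_states
  up <- c(r$kf, 0)      # state i -> i+1
  down <- c(0, r$kb)    # state i -> i-1
  list(exit = up + down, p_up = ifelse(up + down > 0, up / (up + down), 0))
}

#' Exact stochastic simulation of single-molecule state paths
#'
#' Continuous-time Markov chain simulation of `n_molecules` independent
#' molecules under a piecewise-constant voltage protocol. Rates are constant
#' within each protocol segment; at segment boundaries the exponential dwell
#' is redrawn with the new rates, which is exact by memorylessness.
#' Reproducible: the same seed gives bit-identical paths.
#'
#' @inheritParams propagate_occupancy
#' @param n_molecules number of molecules (>= 1).
#' @param seed integer seed.
#' @param initial `"holding"` (each molecule drawn from the equilibrium
#'   distribution at the first segment's voltage) or an occupancy vector used
#'   as the initial-state distribution.
#' @return list of class `gillespie_paths`; element `paths` is a list with,
#'   per molecule, `t` (jump times, ms, starting at 0) and `state` (state
#'   after each jump; `state[1]` is the initial state).
#' @seealso [gillespie_occupancy()] for ensemble occupancies on a time grid
#'   without storing paths.
#' @export
gillespie_sample <- function(scheme, protocol, step = protocol$step_levels[1],
                             n_molecules = 1, seed = 1, initial = "holding") {
  stopifnot(n_molecules >= 1)
  set.seed(seed)
  seg <- protocol_segments(protocol, step)
  jt <- lapply(seg$V, function(v) .jump_table(scheme, v))
  p0 <- if (identical(initial, "holding")) steady_state(scheme, seg$V[1]) else initial
  n <- scheme$n_states
  s0 <- sample.int(n, n_molecules, replace = TRUE, prob = p0)
  paths <- vector("list", n_molecules)
  for (m in seq_len(n_molecules)) {
    tt <- 0
    ss <- s0[m]
    cur <- s0[m]
    tcur <- 0
    for (k in seq_len(nrow(seg))) {
      tend <- seg$t1[k]
      repeat {
        rate <- jt[[k]]$exit[cur]
        if (rate <= 0) { tcur <- tend; break }
        dwell <- stats::rexp(1, rate)
        if (tcur + dwell >= tend) { tcur <- tend; break }
        tcur <- tcur + dwell
        cur <- if (stats::runif(1) < jt[[k]]$p_up[cur]) cur + 1L else cur - 1L
        tt <- c(tt, tcur)
        ss <- c(ss, cur)
      }
    }
    paths[[m]] <- list(t = tt, state = ss)
  }
  structure(list(paths = paths, n_states = n, step = step,
                 total_duration = protocol$total_duration, seed = seed),
            class = "gillespie_paths")
}

#' State of each molecule at given times
#'
#' @param paths a [gillespie_sample()] result.
#' @param times query times, ms.
#' @return n_molecules x length(times) integer matrix of states.
#' @export
states_at <- function(paths, times) {
  out <- matrix(NA_integer_, length(paths$paths), length(times))
  for (m in seq_along(paths$paths)) {
    p <- paths$paths[[m]]
    idx <- findInterval(times, p$t)
    idx[idx < 1L] <- 1L
    out[m, ] <- p$state[idx]
  }
  out
}

#' Dwell times spent in one state
#'
#' Complete (non-censored) dwell intervals in `state` across all molecules;
#' used to check the exponential dwell-time law.
#'
#' @param paths a [gillespie_sample()] result.
#' @param state state index.
#' @return numeric vector of dwell durations, ms.
#' @export
dwell_times <- function(paths, state) {
  unlist(lapply(paths$paths, function(p) {
    d <- diff(c(p$t, paths$total_duration))
    keep <- p$state == state
    keep[length(keep)] <- FALSE    # final interval is right-censored
    d[keep]
  }))
}

#' Ensemble occupancy at query times by vectorized stochastic simulation
#'
#' Same stochastic law as [gillespie_sample()] but advances all molecules in
#' vectorized rounds and records only the state counts at `times`, so large
#' ensembles (tens of thousands of molecules) are cheap. Used as the
#' stochastic oracle for [propagate_occupancy()].
#'
#' @inheritParams gillespie_sample
#' @param times query times, ms.
#' @return length(times) x n_states matrix of occupancy fractions.
#' @export
gillespie_occupancy <- function(scheme, protocol, step = protocol$step_levels[1],
                                n_molecules = 1000, times, seed = 1,
                                initial = "holding") {
  set.seed(seed)
  seg <- protocol_segments(protocol, step)
  p0 <- if (identical(initial, "holding")) steady_state(scheme, seg$V[1]) else initial
  n <- scheme$n_states
  state <- sample.int(n, n_molecules, replace = TRUE, prob = p0)
  ord <- order(times)
  times_s <- times[ord]
  occ <- matrix(0, length(times), n)
  record <- function(h) occ[h, ] <<- tabulate(state, n) / n_molecules
  for (h in which(times_s <= 0)) record(ord[h])
  brk <- sort(unique(c(0, seg$t0, seg$t1, times_s[times_s > 0])))
  brk <- brk[brk >= 0 & brk <= max(seg$t1)]
  for (j in seq_len(length(brk) - 1L)) {
    a <- brk[j]; b <- brk[j + 1L]
    k <- findInterval(a, seg$t0)
    jt <- .jump_table(scheme, seg$V[k])
    tloc <- rep(a, n_molecules)
    active <- which(jt$exit[state] > 0)
    while (length(active)) {
      dw <- stats::rexp(length(active), jt$exit[state[active]])
      tnew <- tloc[active] + dw
      moved <- tnew < b
      im <- active[moved]
      if (!length(im)) break
      goes_up <- stats::runif(length(im)) < jt$p_up[state[im]]
      state[im] <- state[im] + ifelse(goes_up, 1L, -1L)
      tloc[im] <- tnew[moved]
      active <- im[jt$exit[state[im]] > 0]
    }
    for (h in which(times_s == b)) record(ord[h])
  }
  occ
}
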