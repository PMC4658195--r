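# Multi-exponential fitting by variable projection: amplitudes (and offset)
# enter linearly and are solved by least squares at each trial set of time
# constants; the time constants are optimized by Nelder-Mead from several
# deterministic starts. This avoids the convergence fragility of fully
# nonlinear double-exponential fits on electrophysiology traces.

.exp_basis <- function(trel, tau) {
  cbind(1, vapply(tau, function(tt) exp(-trel / tt), numeric(length(trel))))
}

.varpro_rss <- function(log_tau, trel, y) {
  tau <- exp(log_tau)
  if (any(tau <= 0) || any(!is.finite(tau))) return(Inf)
  X <- .exp_basis(trel, tau)
  fit <- tryCatch(stats::lm.fit(X, y), error = function(e) NULL)
  if (is.null(fit)) return(Inf)
  sum(fit$residuals^2)
}

# crude single time-constant estimate from the area under the relaxation
.tau_guess <- function(trel, y) {
  yinf <- mean(y[trel >= stats::quantile(trel, 0.8)])
  y0 <- y[1]
  if (abs(y0 - yinf) < .Machine$double.eps * 10) return(diff(range(trel)) / 5)
  area <- sum(diff(trel) * (head(y, -1) + tail(y, -1)) / 2 - diff(trel) * yinf)
  tau <- abs(area / (y0 - yinf))
  max(min(tau, diff(range(trel))), trel[2] - trel[1])
}

#' Fit a sum of exponentials plus offset to a trace segment
#'
#' Fits `y(t) = C + sum_i A_i exp(-(t - t0)/tau_i)` with `t0` the first time
#' in the window, for 1 or 2 components, and reports the amplitude-weighted
#' time constant `tau_w = sum(|A_i| tau_i) / sum(|A_i|)`. Components are
#' ordered fast-first. Deterministic multi-start (the area-based guess and
#' guess/5), ties broken by residual RMS.
#'
#' @param time time vector, ms.
#' @param y trace values over `time`.
#' @param n_components 1 or 2.
#' @param max_points traces longer than this are uniformly thinned before
#'   fitting (the decay is smooth; thinning is unbiased).
#' @param maxit Nelder-Mead iteration cap per start.
#' @return object of class `exp_decay_fit`: `components` (data.frame with
#'   `amplitude`, `tau`, fast first), `offset`, `tau_w`, `rss`, `rms`,
#'   `t0`, and `predict(t)` closure.
#' @export
fit_exp_decay <- function(time, y, n_components = 2, max_points = 200,
                          maxit = 200) {
  stopifnot(length(time) == length(y), length(y) >= n_components * 2 + 2)
  if (length(y) > max_points) {
    idx <- unique(round(seq(1, length(y), length.out = max_points)))
    time <- time[idx]; y <- y[idx]
  }
  t0 <- time[1]
  trel <- time - t0
  tg <- .tau_guess(trel, y)
  starts <- if (n_components == 1) {
    list(log(tg), log(tg / 5), log(tg * 4))
  } else {
    list(log(c(tg, tg / 5)), log(c(tg * 3, tg / 2)))
  }
  best <- NULL
  if (n_components == 1) {
    span <- log(c(max(tg / 200, trel[2] / 10), diff(range(trel)) * 20))
    opt <- stats::optimize(function(lt) .varpro_rss(lt, trel, y),
                           interval = span, tol = 1e-10)
    best <- list(par = opt$minimum, value = opt$objective)
  } else {
    for (s in starts) {
      opt <- stats::optim(s, .varpro_rss, trel = trel, y = y,
                          method = "Nelder-Mead",
                          control = list(maxit = maxit, reltol = 1e-10))
      if (is.null(best) || opt$value < best$value) best <- opt
    }
  }
  tau <- exp(best$par)
  X <- .exp_basis(trel, tau)
  beta <- stats::lm.fit(X, y)$coefficients
  comp <- data.frame(amplitude = unname(beta[-1]), tau = tau)
  comp <- comp[order(comp$tau), , drop = FALSE]
  rownames(comp) <- NULL
  aw <- abs(comp$amplitude)
  tau_w <- if (sum(aw) > 0) sum(aw * comp$tau) / sum(aw) else mean(comp$tau)
  offset <- unname(beta[1])
  pred <- function(t) {
    out <- rep(offset, length(t))
    for (i in seq_len(nrow(comp))) {
      out <- out + comp$amplitude[i] * exp(-(t - t0) / comp$tau[i])
    }
    out
  }
  rss <- best$value
  structure(list(components = comp, offset = offset, tau_w = tau_w,
                 rss = rss, rms = sqrt(rss / length(y)), t0 = t0,
                 n_points = length(y), predict = pred),
            class = "exp_decay_fit")
}

#' @export
print.exp_decay_fit <- function(x, ...) {
  cat(sprintf("<exp_decay_fit: %d component(s), tau_w = %.3g ms, rms = %.3g>\n",
              nrow(x$components), x$tau_w, x$rms))
  print(x$components, row.names = FALSE)
  invisible(x)
}
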