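#' Morphological background correction of a movie
#'
#' Subtracts the per-frame grayscale opening (erosion then dilation with a
#' disc structuring element) from each frame: smooth background structure is
#' removed while point sources, which are narrower than the disc, are
#' preserved.
#'
#' @param movie a `movie_stack` (see [render_movie()]) or a single matrix.
#' @param radius disc radius in pixels; must exceed the PSF sigma.
#' @return background-corrected object of the same shape.
#' @export
morphological_background <- function(movie, radius = 5) {
  single <- is.matrix(movie)
  frames <- if (single) list(movie) else movie$frames
  fs <- nrow(frames[[1]])
  if (radius >= fs) stop("structuring-element radius exceeds the field size")
  brush <- EBImage::makeBrush(2 * radius + 1, shape = "disc")
  corr <- lapply(frames, function(f) {
    # grayscale opening commutes with affine rescaling; EBImage operates on
    # the [0, 1] intensity range
    rng <- range(f)
    if (rng[2] <= rng[1]) return(f - f)
    fs <- (f - rng[1]) / (rng[2] - rng[1])
    f - (EBImage::opening(fs, brush) * (rng[2] - rng[1]) + rng[1])
  })
  if (single) return(corr[[1]])
  movie$frames <- corr
  movie
}

#' Mean image of a movie
#' @param movie a `movie_stack`.
#' @return matrix (pixel-wise mean over frames).
#' @export
mean_image <- function(movie) {
  Reduce(`+`, movie$frames) / length(movie$frames)
}

#' Detect point emitters in an image
#'
#' Local maxima above `median + threshold_k * MAD` of the image, pruned
#' greedily (brightest first) so that no two detections are closer than
#' `min_separation`. Run on a background-corrected mean image.
#'
#' @param image matrix (background-corrected).
#' @param threshold_k detection threshold in MAD multiples (default 6).
#' @param min_separation minimum pairwise distance, pixels.
#' @return data.frame with `x`, `y` (pixels) and `intensity`, brightest
#'   first; zero rows if nothing is found.
#' @export
detect_spots <- function(image, threshold_k = 6, min_separation = 4) {
  thr <- stats::median(image) + threshold_k * stats::mad(image)
  n <- nrow(image); m <- ncol(image)
  # 8-neighbourhood local maxima (strictly greater than or equal, interior only)
  cand <- which(image > thr, arr.ind = TRUE)
  cand <- cand[cand[, 1] > 1 & cand[, 1] < n & cand[, 2] > 1 & cand[, 2] < m, ,
               drop = FALSE]
  if (!nrow(cand)) {
    return(data.frame(x = numeric(0), y = numeric(0), intensity = numeric(0)))
  }
  is_max <- vapply(seq_len(nrow(cand)), function(i) {
    r <- cand[i, 1]; c <- cand[i, 2]
    image[r, c] >= max(image[(r - 1):(r + 1), (c - 1):(c + 1)])
  }, logical(1))
  cand <- cand[is_max, , drop = FALSE]
  if (!nrow(cand)) {
    return(data.frame(x = numeric(0), y = numeric(0), intensity = numeric(0)))
  }
  val <- image[cand]
  ord <- order(val, decreasing = TRUE)
  cand <- cand[ord, , drop = FALSE]; val <- val[ord]
  keep <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    if (!any(keep)) { keep[i] <- TRUE; next }
    d2 <- (cand[keep, 1] - cand[i, 1])^2 + (cand[keep, 2] - cand[i, 2])^2
    if (min(d2) >= min_separation^2) keep[i] <- TRUE
  }
  # image convention: x = column, y = row (matching render_movie positions)
  data.frame(x = cand[keep, 2], y = cand[keep, 1], intensity = val[keep])
}

#' Aperture photometry of one spot across a movie
#'
#' Per-frame summed intensity inside a circular aperture minus the annulus
#' median background scaled by the aperture area.
#'
#' @param movie a `movie_stack`.
#' @param position `c(x, y)` in pixels.
#' @param aperture_radius aperture radius, pixels (default 2x PSF sigma
#'   rounded up).
#' @param annulus_radii inner and outer background annulus radii, pixels.
#' @return object of class `spot_trace` with `time`, `adu` (background
#'   subtracted), `background_adu` (annulus median), `position`,
#'   `clipped` flag when the aperture touches the field edge.
#' @export
extract_trace <- function(movie, position, aperture_radius = NULL,
                          annulus_radii = NULL) {
  sig <- movie$camera$psf_sigma
  if (is.null(aperture_radius)) aperture_radius <- ceiling(2 * sig)
  if (is.null(annulus_radii)) annulus_radii <- c(4 * sig, 6 * sig)
  fs <- nrow(movie$frames[[1]])
  x <- position[1]; y <- position[2]
  clipped <- x - aperture_radius < 1 || x + aperture_radius > fs ||
    y - aperture_radius < 1 || y + aperture_radius > fs
  if (clipped) warning("aperture clipped by the field edge")
  xg <- matrix(rep(seq_len(fs), each = fs), fs)
  yg <- matrix(rep(seq_len(fs), times = fs), fs)
  d2 <- (xg - x)^2 + (yg - y)^2
  ap <- d2 <= aperture_radius^2
  an <- d2 >= annulus_radii[1]^2 & d2 <= annulus_radii[2]^2
  n_ap <- sum(ap)
  adu <- numeric(length(movie$frames))
  bgm <- numeric(length(movie$frames))
  for (f in seq_along(movie$frames)) {
    fr <- movie$frames[[f]]
    bgm[f] <- stats::median(fr[an])
    adu[f] <- sum(fr[ap]) - bgm[f] * n_ap
  }
  dt <- movie$frame_interval
  structure(list(time = (seq_along(adu) - 0.5) * dt, adu = adu,
                 background_adu = bgm, position = position,
                 aperture_radius = aperture_radius,
                 frame_interval = dt, clipped = clipped),
            class = "spot_trace")
}

#' Sample autocorrelation with white-noise confidence band
#'
#' `r(k) = sum (x_t - xbar)(x_{t+k} - xbar) / sum (x_t - xbar)^2` for lags
#' 0..`max_lag`, with the approximate 95% band `+/- 1.96/sqrt(n)` for a
#' Gaussian white-noise process. Use an unfiltered, stationary segment (no
#' voltage step inside).
#'
#' @param trace numeric vector (intensity samples).
#' @param max_lag maximum lag in samples.
#' @param detrend `"none"` or `"linear"` (removes a fitted line first).
#' @return object of class `autocorr_result`: `lags`, `r`, `band`,
#'   `n_samples`, `n_exceed` (band-exceeding lags among 1..max_lag).
#' @export
autocorrelation <- function(trace, max_lag = 50,
                            detrend = c("none", "linear")) {
  detrend <- match.arg(detrend)
  n <- length(trace)
  if (n < 10 * max_lag) {
    warning("segment shorter than 10x max_lag; autocorrelation will be noisy")
  }
  x <- trace
  if (detrend == "linear") {
    tt <- seq_along(x)
    x <- stats::lm.fit(cbind(1, tt), x)$residuals
  }
  r <- as.vector(stats::acf(x, lag.max = max_lag, plot = FALSE,
                            demean = TRUE)$acf)
  band <- 1.96 / sqrt(n)
  structure(list(lags = 0:max_lag, r = r, band = band, n_samples = n,
                 n_exceed = sum(abs(r[-1]) > band)),
            class = "autocorr_result")
}

#' @export
print.autocorr_result <- function(x, ...) {
  cat(sprintf("<autocorr_result: n = %d, band = +/-%.4f, %d/%d lags exceed>\n",
              x$n_samples, x$band, x$n_exceed, length(x$lags) - 1))
  invisible(x)
}

#' Binomial test for fluctuation (non-white) noise
#'
#' Under white noise each non-zero lag exceeds the 95% band independently
#' with probability 0.05; the observed count of band-exceeding lags among
#' the first `L` is referred to the binomial upper tail, and the trace is
#' called "fluctuating" when that tail probability is below `alpha`.
#'
#' @param ac an [autocorrelation()] result.
#' @param L number of leading non-zero lags to test (1 <= L <= max lag).
#' @param alpha verdict threshold on the binomial tail p (default 0.01).
#' @return list with `p_value`, `n_exceed`, `L`, `fluctuating`.
#' @export
fluctuation_test <- function(ac, L = 20, alpha = 0.01) {
  if (L < 1 || L > length(ac$lags) - 1) {
    stop("L must lie in 1..max_lag")
  }
  k <- sum(abs(ac$r[2:(L + 1)]) > ac$band)
  p <- stats::pbinom(k - 1, L, 0.05, lower.tail = FALSE)
  list(p_value = p, n_exceed = k, L = L, fluctuating = p < alpha)
}

#' Average single-molecule traces after per-trace baseline subtraction
#'
#' Per-frame mean of the traces after removing a linear baseline fitted to
#' each trace's quiescent regions (or the full trace when none are given).
#' Summing many voltage-responding single-molecule traces recapitulates the
#' macroscopic fluorescence response.
#'
#' @param traces list of `spot_trace` objects with identical frame timing.
#' @param baseline_regions list of `c(start, end)` windows (ms) used for the
#'   per-trace linear baseline, or `NULL` to use the whole trace.
#' @return a `spot_trace`-like list with the mean trace in `adu`.
#' @export
aggregate_traces <- function(traces, baseline_regions = NULL) {
  stopifnot(length(traces) >= 1)
  t0 <- traces[[1]]$time
  for (tr in traces) {
    if (length(tr$time) != length(t0) || max(abs(tr$time - t0)) > 1e-9) {
      stop("traces do not share protocol timing")
    }
  }
  mat <- vapply(traces, function(tr) {
    y <- tr$adu
    if (is.null(baseline_regions)) {
      cf <- stats::lm.fit(cbind(1, t0), y)$coefficients
    } else {
      sel <- Reduce(`|`, lapply(baseline_regions,
                                function(w) t0 >= w[1] & t0 < w[2]))
      cf <- stats::lm.fit(cbind(1, t0[sel]), y[sel])$coefficients
    }
    y - (cf[1] + cf[2] * t0)
  }, numeric(length(t0)))
  structure(list(time = t0, adu = rowMeans(mat),
                 n_traces = length(traces),
                 frame_interval = traces[[1]]$frame_interval),
            class = "spot_trace")
}
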