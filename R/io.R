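#' Write a sweep trace to a two-column CSV with metadata header
#'
#' Format: `#`-prefixed `key: value` header lines (`channel`, `units`,
#' `voltage_mV`, `sample_interval_ms`, plus any extras), then a
#' `time_ms,value` table at full double precision.
#'
#' @param path output file.
#' @param time time vector, ms.
#' @param value trace values.
#' @param channel channel name (e.g. `"gating"`, `"fluorescence"`, `"vm"`).
#' @param units unit string.
#' @param voltage_mV step voltage of the sweep.
#' @param extra named list of extra metadata entries.
#' @export
write_sweep <- function(path, time, value, channel, units, voltage_mV,
                        extra = list()) {
  stopifnot(length(time) == length(value))
  dt <- if (length(time) > 1) time[2] - time[1] else NA_real_
  meta <- c(list(channel = channel, units = units, voltage_mV = voltage_mV,
                 sample_interval_ms = dt), extra)
  con <- file(path, "w")
  on.exit(close(con))
  for (k in names(meta)) {
    writeLines(sprintf("# %s: %s", k, format(meta[[k]], digits = 17)), con)
  }
  writeLines("time_ms,value", con)
  writeLines(sprintf("%.17g,%.17g", time, value), con)
  invisible(path)
}

#' Read a sweep CSV written by [write_sweep()]
#'
#' @param path input file.
#' @return list with `time`, `value` and `meta` (named list; numeric values
#'   converted).
#' @export
read_sweep <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines)
  if (length(hdr) && any(diff(hdr) != 1)) {
    stop("malformed header: metadata lines must be contiguous at the top")
  }
  meta <- list()
  for (i in hdr) {
    m <- regmatches(lines[i], regexec("^#\\s*([^:]+):\\s*(.*)$", lines[i]))[[1]]
    if (length(m) != 3) {
      stop(sprintf("malformed metadata at line %d: '%s'", i, lines[i]))
    }
    key <- trimws(m[2]); val <- trimws(m[3])
    nval <- suppressWarnings(as.numeric(val))
    meta[[key]] <- if (!is.na(nval)) nval else val
  }
  for (req in c("channel", "units", "voltage_mV", "sample_interval_ms")) {
    if (is.null(meta[[req]])) {
      stop(sprintf("missing required '#%s' header in %s", req, path))
    }
  }
  body <- utils::read.csv(text = lines[-hdr], header = TRUE)
  if (!all(c("time_ms", "value") %in% names(body))) {
    stop("sweep body must have columns time_ms,value")
  }
  list(time = body$time_ms, value = body$value, meta = meta)
}

#' Write a full recording as per-sweep CSVs plus a JSON manifest
#'
#' @param recording a [simulate_macroscopic_recording()] result.
#' @param dir output directory.
#' @return invisibly, the manifest path.
#' @export
write_recording <- function(recording, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  pr <- recording$protocol
  for (s in names(recording$sweeps)) {
    sw <- recording$sweeps[[s]]
    for (ch in c("gating", "fluorescence", "vm")) {
      units <- switch(ch, gating = "e0_per_ms", fluorescence = "photodiode_au",
                      vm = "mV")
      write_sweep(file.path(dir, sprintf("%s_%s.csv", ch, s)),
                  sw$time, sw[[ch]], ch, units, as.numeric(s))
    }
  }
  manifest <- list(
    scheme = recording$scheme_name, seed = recording$seed,
    n_molecules = recording$n_molecules,
    noise = unclass(recording$noise),
    protocol = list(holding = pr$holding, step_levels = pr$step_levels,
                    step_onset = pr$step_onset,
                    step_duration = pr$step_duration,
                    total_duration = pr$total_duration,
                    sample_interval = pr$sample_interval),
    package_version = as.character(utils::packageVersion("gevikin")),
    written = format(Sys.time(), tz = "UTC")
  )
  mp <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(mp)
}

#' Read a recording directory written by [write_recording()]
#'
#' @param dir recording directory.
#' @return a `vcf_recording`-like list (traces and protocol restored).
#' @export
read_recording <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  pr <- do.call(voltage_protocol,
                manifest$protocol[c("holding", "step_levels", "step_onset",
                                    "step_duration", "total_duration",
                                    "sample_interval")])
  sweeps <- list()
  for (s in pr$step_levels) {
    sw <- list()
    for (ch in c("gating", "fluorescence", "vm")) {
      d <- read_sweep(file.path(dir, sprintf("%s_%s.csv", ch, s)))
      sw$time <- d$time
      sw[[ch]] <- d$value
    }
    sweeps[[as.character(s)]] <- sw
  }
  structure(list(protocol = pr, sweeps = sweeps,
                 scheme_name = manifest$scheme,
                 n_molecules = manifest$n_molecules,
                 noise = do.call(noise_model, manifest$noise[
                   c("gating_sd", "leak_slope", "cap_amp", "cap_tau",
                     "fluor_sd", "bleach", "bleach_rate", "tau_bleach")]),
                 seed = manifest$seed),
            class = "vcf_recording")
}

#' Write a spot trace to CSV
#' @param trace a `spot_trace`.
#' @param path output file.
#' @export
write_spot_trace <- function(trace, path) {
  bg <- trace$background_adu %||% rep(NA_real_, length(trace$adu))
  utils::write.csv(data.frame(frame_ms = trace$time, adu = trace$adu,
                              background_adu = bg),
                   path, row.names = FALSE)
  invisible(path)
}
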