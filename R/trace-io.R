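#' Force trace objects
#'
#' A `force_trace` holds a uniformly sampled force time series from a
#' force-sensitive resistor, together with its sample rate, unit state and
#' recording identity. Traces start life in raw sensor units and are converted
#' to Newtons exactly once by [calibrate()]; downstream tap detection requires
#' Newtons. `start_sample` records the original-recording index of the first
#' retained sample so that landmark times stay in original-recording
#' coordinates after [trim_edges()].
#'
#' @param samples Numeric vector of force readings (one channel).
#' @param sample_rate_hz Sampling rate in Hz (nominally 3000).
#' @param units Either `"raw"` (uncalibrated sensor units) or `"newton"`.
#' @param recording_id Character label identifying the recording.
#' @param start_sample Zero-based index, in the original recording, of the
#'   first sample held here.
#'
#' @return An object of class `force_trace`.
#' @export
force_trace <- function(samples, sample_rate_hz, units = c("raw", "newton"),
                        recording_id = "trace", start_sample = 0L) {
  units <- match.arg(units)
  if (!is.numeric(samples) || length(samples) < 1L) {
    stop("'samples' must be a non-empty numeric vector", call. = FALSE)
  }
  if (anyNA(samples)) stop("'samples' must not contain NA", call. = FALSE)
  if (!is.numeric(sample_rate_hz) || length(sample_rate_hz) != 1L ||
      !is.finite(sample_rate_hz) || sample_rate_hz <= 0) {
    stop("'sample_rate_hz' must be a single positive number", call. = FALSE)
  }
  structure(
    list(
      samples = as.numeric(samples),
      sample_rate_hz = as.numeric(sample_rate_hz),
      units = units,
      recording_id = as.character(recording_id)[1L],
      start_sample = as.integer(start_sample)
    ),
    class = "force_trace"
  )
}

#' @export
print.force_trace <- function(x, ...) {
  dur <- length(x$samples) / x$sample_rate_hz
  cat(sprintf(
    "<force_trace '%s': %d samples @ %g Hz (%.2f s), units = %s, start sample %d>\n",
    x$recording_id, length(x$samples), x$sample_rate_hz, dur, x$units,
    x$start_sample
  ))
  invisible(x)
}

#' @export
length.force_trace <- function(x) length(x$samples)

#' Times of trace samples in original-recording coordinates
#'
#' @param trace A [force_trace()].
#' @return Numeric vector of per-sample times in ms, honouring `start_sample`.
#' @export
trace_times_ms <- function(trace) {
  stopifnot(inherits(trace, "force_trace"))
  (trace$start_sample + seq_along(trace$samples) - 1L) / trace$sample_rate_hz * 1000
}

#' Write a force trace to a plain-text file
#'
#' The format is TSV with `#`-prefixed header lines declaring
#' `sample_rate_hz`, `units`, `recording_id`, `start_sample` and `channels`,
#' followed by two columns (`sample`, `force`). Round-trip through
#' [read_trace()] is lossless.
#'
#' @param trace A [force_trace()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path) {
  stopifnot(inherits(trace, "force_trace"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# sample_rate_hz: %.10g", trace$sample_rate_hz),
    sprintf("# units: %s", trace$units),
    sprintf("# recording_id: %s", trace$recording_id),
    sprintf("# start_sample: %d", trace$start_sample),
    "# channels: force",
    "sample\tforce"
  ), con)
  df <- data.frame(
    sample = trace$start_sample + seq_along(trace$samples) - 1L,
    force = format(trace$samples, digits = 17, trim = TRUE, scientific = FALSE)
  )
  utils::write.table(df, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a force trace written by [write_trace()]
#'
#' @param path Path to a trace file.
#' @return A [force_trace()].
#' @export
read_trace <- function(path) {
  if (!file.exists(path)) stop("trace file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  if (length(lines) == 0L) {
    stop("trace format error: file is empty: ", path, call. = FALSE)
  }
  hdr_idx <- grep("^#", lines)
  header <- list()
  for (i in hdr_idx) {
    m <- regmatches(lines[i], regexec("^#\\s*([A-Za-z_]+)\\s*:\\s*(.*)$", lines[i]))[[1L]]
    if (length(m) == 3L) header[[m[2L]]] <- trimws(m[3L])
  }
  for (field in c("sample_rate_hz", "units")) {
    if (is.null(header[[field]])) {
      stop(sprintf("trace format error: missing header field '%s' in %s",
                   field, path), call. = FALSE)
    }
  }
  body <- lines[setdiff(seq_along(lines), hdr_idx)]
  body <- body[nzchar(trimws(body))]
  if (length(body) > 0L && grepl("^sample\\b", body[1L])) body <- body[-1L]
  if (length(body) == 0L) {
    stop("trace format error: no samples in ", path, call. = FALSE)
  }
  parts <- strsplit(body, "\t", fixed = TRUE)
  force <- suppressWarnings(vapply(parts, function(p) as.numeric(p[[2L]]), 0))
  if (anyNA(force)) {
    bad <- which(is.na(force))[1L]
    stop(sprintf("trace format error: non-numeric sample at data line %d of %s",
                 bad, path), call. = FALSE)
  }
  start_sample <- if (!is.null(header$start_sample)) {
    as.integer(header$start_sample)
  } else {
    as.integer(suppressWarnings(as.numeric(parts[[1L]][[1L]])))
  }
  if (is.na(start_sample)) start_sample <- 0L
  force_trace(
    samples = force,
    sample_rate_hz = as.numeric(header$sample_rate_hz),
    units = header$units,
    recording_id = if (is.null(header$recording_id)) "trace" else header$recording_id,
    start_sample = start_sample
  )
}

#' Calibration table mapping raw sensor readings to Newtons
#'
#' @param raw Strictly increasing numeric vector of raw sensor values.
#' @param newton Non-negative, non-decreasing forces (N) at those raw values.
#' @return An object of class `calibration_table`.
#' @export
calibration_table <- function(raw, newton) {
  if (length(raw) != length(newton) || length(raw) < 2L) {
    stop("calibration error: table needs at least 2 (raw, newton) pairs",
         call. = FALSE)
  }
  if (any(diff(raw) <= 0)) {
    stop("calibration error: raw values must be strictly increasing",
         call. = FALSE)
  }
  if (any(newton < 0) || any(diff(newton) < 0)) {
    stop("calibration error: forces must be non-negative and non-decreasing",
         call. = FALSE)
  }
  structure(list(raw = as.numeric(raw), newton = as.numeric(newton)),
            class = "calibration_table")
}

#' Read a calibration table from a two-column CSV
#'
#' The CSV must have columns `raw` and `newton`.
#'
#' @param path Path to a CSV file.
#' @return A [calibration_table()].
#' @export
read_calibration <- function(path) {
  df <- utils::read.csv(path)
  if (!all(c("raw", "newton") %in% names(df))) {
    stop("calibration error: CSV needs columns 'raw' and 'newton'",
         call. = FALSE)
  }
  calibration_table(df$raw, df$newton)
}

#' Convert a raw force trace into Newtons
#'
#' Each sample is mapped through piecewise-linear interpolation over the
#' calibration table; raw values outside the table's range are clamped to the
#' end forces. Calibration is applied exactly once (raw -> newton).
#'
#' @param trace A [force_trace()] with `units = "raw"`.
#' @param table A [calibration_table()].
#' @return The calibrated trace with `units = "newton"`.
#' @export
calibrate <- function(trace, table) {
  stopifnot(inherits(trace, "force_trace"), inherits(table, "calibration_table"))
  if (trace$units != "raw") {
    stop("calibrate() expects a raw trace; units are already '", trace$units,
         "'", call. = FALSE)
  }
  out <- trace
  out$samples <- stats::approx(table$raw, table$newton, xout = trace$samples,
                               rule = 2, ties = "ordered")$y
  out$units <- "newton"
  out
}

#' Discard the first and last part of a recording
#'
#' Removes `floor(trim_s * sample_rate)` samples from each end of the trace,
#' mirroring the preprocessing step that discards the settling period at the
#' start and end of each recording. The trimmed trace's `start_sample` is
#' advanced so that detected landmark times remain in original-recording
#' coordinates.
#'
#' @param trace A [force_trace()].
#' @param trim_s Seconds to remove from each end (default 0.5).
#' @return The trimmed trace.
#' @export
trim_edges <- function(trace, trim_s = 0.5) {
  stopifnot(inherits(trace, "force_trace"))
  if (trim_s < 0) stop("trim error: trim_s must be >= 0", call. = FALSE)
  k <- floor(trim_s * trace$sample_rate_hz)
  n <- length(trace$samples)
  if (n <= 2L * k) {
    stop(sprintf("trim error: trace of %d samples too short to trim %d from each end",
                 n, k), call. = FALSE)
  }
  if (k == 0L) return(trace)
  out <- trace
  out$samples <- trace$samples[(k + 1L):(n - k)]
  out$start_sample <- trace$start_sample + as.integer(k)
  out
}

# Triangular (Bartlett) kernel with non-zero end taps, normalized to unit sum.
# For window 3 this is c(0.25, 0.5, 0.25).
bartlett_kernel <- function(window_samples) {
  half <- (window_samples + 1) / 2
  w <- 1 - abs(seq_len(window_samples) - half) / half
  w / sum(w)
}

#' Smooth a force trace with a Bartlett (triangular) window
#'
#' Centered convolution with a unit-sum triangular kernel; edges are handled
#' by reflecting the signal, so output length equals input length and constant
#' signals are fixed points. The default 160-sample window corresponds to
#' roughly 53 ms at a 3 kHz sample rate.
#'
#' @param trace A [force_trace()].
#' @param window_samples Window length in samples (default 160).
#' @return The smoothed trace.
#' @export
smooth_bartlett <- function(trace, window_samples = 160L) {
  stopifnot(inherits(trace, "force_trace"))
  window_samples <- as.integer(window_samples)
  if (window_samples < 1L) {
    stop("smoothing error: window_samples must be >= 1", call. = FALSE)
  }
  n <- length(trace$samples)
  if (window_samples > n) {
    stop(sprintf("smoothing error: window (%d) longer than trace (%d)",
                 window_samples, n), call. = FALSE)
  }
  if (window_samples == 1L) return(trace)
  k <- window_samples
  w <- bartlett_kernel(k)
  left <- (k - 1L) %/% 2L
  right <- k - 1L - left
  x <- trace$samples
  padded <- c(rev(x[seq_len(left) + 1L]), x, x[n - seq_len(right)])
  # out[i] = sum_j w[j] * padded[i + j - 1]; the kernel is palindromic, so a
  # one-sided recursive filter evaluated at a shifted index gives exactly this.
  y <- stats::filter(padded, w, method = "convolution", sides = 1L)
  out <- trace
  out$samples <- as.numeric(y[k:(k + n - 1L)])
  out
}

#' Standard preprocessing pipeline for a raw recording
#'
#' Applies, in order: edge trimming, calibration to Newtons, Bartlett
#' smoothing. This fixed order mirrors the acquisition script's preprocessing
#' sequence; trimming before smoothing keeps the settling transients out of
#' the convolution entirely.
#'
#' @param trace A raw [force_trace()].
#' @param calibration A [calibration_table()], or `NULL` if the trace is
#'   already in Newtons.
#' @param trim_s Seconds trimmed from each end (default 0.5).
#' @param window_samples Bartlett window length in samples (default 160).
#' @return A trimmed, calibrated, smoothed `force_trace` in Newtons.
#' @export
preprocess_trace <- function(trace, calibration = NULL, trim_s = 0.5,
                             window_samples = 160L) {
  out <- trim_edges(trace, trim_s)
  if (!is.null(calibration)) out <- calibrate(out, calibration)
  if (out$units != "newton") {
    stop("preprocess_trace(): raw trace requires a calibration table",
         call. = FALSE)
  }
  smooth_bartlett(out, window_samples)
}
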