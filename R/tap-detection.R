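#' Tap detection configuration
#'
#' Parameters of the threshold-plus-refractory landmarking rules. A tap onset
#' fires when the smoothed force rises above `threshold_n` (strictly greater;
#' 0.05 N by default). The matching offset fires at the first sample where the
#' force drops back below threshold at least `min_offset_after_onset_ms` after
#' that onset, and the next onset may fire at the earliest
#' `min_onset_after_offset_ms` after the previous offset. Recordings from
#' patients who tapped very softly (or partly off the sensor) can carry a
#' per-recording `threshold_override_n`; the override and its reason are kept
#' in the detection output so the adjustment is auditable rather than
#' interactive.
#'
#' @param threshold_n Onset/offset force threshold in Newtons (default 0.05).
#' @param min_offset_after_onset_ms Offset refractory time in ms (default 40).
#' @param min_onset_after_offset_ms Onset refractory time in ms (default 75).
#' @param threshold_override_n Optional per-recording threshold replacing
#'   `threshold_n`.
#' @param override_note Provenance note explaining the override.
#' @return An object of class `detection_config`.
#' @export
detection_config <- function(threshold_n = 0.05,
                             min_offset_after_onset_ms = 40,
                             min_onset_after_offset_ms = 75,
                             threshold_override_n = NULL,
                             override_note = NULL) {
  if (threshold_n <= 0) stop("threshold_n must be > 0", call. = FALSE)
  if (min_offset_after_onset_ms < 0 || min_onset_after_offset_ms < 0) {
    stop("refractory times must be >= 0", call. = FALSE)
  }
  if (!is.null(threshold_override_n) && threshold_override_n <= 0) {
    stop("threshold_override_n must be > 0", call. = FALSE)
  }
  structure(
    list(
      threshold_n = threshold_n,
      min_offset_after_onset_ms = min_offset_after_onset_ms,
      min_onset_after_offset_ms = min_onset_after_offset_ms,
      threshold_override_n = threshold_override_n,
      override_note = override_note
    ),
    class = "detection_config"
  )
}

#' Detect tap onset and offset landmarks on a preprocessed force trace
#'
#' Scans the trace forward. An onset fires at the first sample where the force
#' crosses strictly above threshold, provided the onset refractory time has
#' elapsed since the previous offset; the matching offset fires at the first
#' sample where the force drops strictly below threshold, provided the offset
#' refractory time has elapsed since that onset. Brief dips below threshold
#' inside the offset refractory window do not terminate a tap. A trailing
#' onset with no qualifying offset before the end of the trace is discarded.
#' Each event carries its peak force (maximum between onset and offset) and
#' dwell time (offset minus onset).
#'
#' @param trace A [force_trace()] in Newtons (preprocess first; see
#'   [preprocess_trace()]).
#' @param config A [detection_config()].
#' @return A `data.frame` of class `tap_events` with columns `onset_ms`,
#'   `offset_ms`, `peak_force_n`, `dwell_ms` (times in original-recording
#'   coordinates), plus attributes `recording_id`, `threshold_n` and
#'   `override_note`.
#' @export
detect_taps <- function(trace, config = detection_config()) {
  stopifnot(inherits(trace, "force_trace"), inherits(config, "detection_config"))
  if (trace$units != "newton") {
    stop("detect_taps() requires a calibrated trace (units = 'newton'); got '",
         trace$units, "'", call. = FALSE)
  }
  thr <- if (!is.null(config$threshold_override_n)) {
    config$threshold_override_n
  } else {
    config$threshold_n
  }
  x <- trace$samples
  n <- length(x)
  ms_per_sample <- 1000 / trace$sample_rate_hz
  above <- x > thr
  below <- x < thr
  off_ref <- ceiling(config$min_offset_after_onset_ms / ms_per_sample)
  on_ref <- ceiling(config$min_onset_after_offset_ms / ms_per_sample)

  onset_i <- integer(0)
  offset_i <- integer(0)
  pos <- 1L
  repeat {
    # next onset: first supra-threshold sample once the onset refractory from
    # the previous offset has elapsed
    hit <- which(above[pos:n])
    if (length(hit) == 0L) break
    onset <- pos + hit[1L] - 1L
    # matching offset: first sub-threshold sample at least the offset
    # refractory after the onset; brief earlier dips are thereby ignored
    from <- onset + off_ref
    if (from > n) break
    hit <- which(below[from:n])
    if (length(hit) == 0L) break # trailing onset without offset: discarded
    offset <- from + hit[1L] - 1L
    onset_i <- c(onset_i, onset)
    offset_i <- c(offset_i, offset)
    pos <- offset + on_ref
    if (pos > n) break
  }

  t0 <- trace$start_sample
  peak <- vapply(seq_along(onset_i),
                 function(j) max(x[onset_i[j]:offset_i[j]]), 0)
  out <- data.frame(
    onset_ms = (t0 + onset_i - 1L) * ms_per_sample,
    offset_ms = (t0 + offset_i - 1L) * ms_per_sample,
    peak_force_n = peak,
    dwell_ms = (offset_i - onset_i) * ms_per_sample
  )
  class(out) <- c("tap_events", "data.frame")
  attr(out, "recording_id") <- trace$recording_id
  attr(out, "threshold_n") <- thr
  attr(out, "override_note") <- config$override_note
  out
}

#' Inter-tap intervals from detected taps
#'
#' Intervals are onset-to-onset differences of adjacent taps; `n` taps yield
#' `n - 1` intervals. All intervals start out flagged `"kept"`; the
#' physiological filter [filter_itis()] reflags rather than deletes, so the
#' audit trail is preserved.
#'
#' @param taps A `tap_events` data frame (or anything with an `onset_ms`
#'   column), sorted by onset.
#' @return An `iti_series` data frame with columns `interval_ms` and `flag`.
#' @export
extract_itis <- function(taps) {
  onsets <- taps$onset_ms
  if (is.unsorted(onsets, strictly = FALSE)) {
    stop("extract_itis(): taps must be sorted by onset", call. = FALSE)
  }
  iv <- if (length(onsets) >= 2L) diff(onsets) else numeric(0)
  iti_series(iv)
}

#' Construct an inter-tap-interval series
#'
#' @param interval_ms Numeric vector of onset-to-onset intervals in ms.
#' @param flag Per-interval flags, one of `"kept"`, `"too_short"`,
#'   `"too_long"`.
#' @return An `iti_series` data frame.
#' @export
iti_series <- function(interval_ms, flag = rep("kept", length(interval_ms))) {
  stopifnot(length(flag) == length(interval_ms),
            all(flag %in% c("kept", "too_short", "too_long")))
  out <- data.frame(interval_ms = as.numeric(interval_ms),
                    flag = as.character(flag))
  class(out) <- c("iti_series", "data.frame")
  out
}

#' Kept intervals of an ITI series
#'
#' @param series An `iti_series`.
#' @return Numeric vector of intervals flagged `"kept"`.
#' @export
kept_itis <- function(series) {
  series$interval_ms[series$flag == "kept"]
}

#' Flag physiologically implausible inter-tap intervals
#'
#' Intervals longer than `max_ms` reflect pauses or interruptions rather than
#' motor capacity, and intervals shorter than `min_ms` are overwhelmingly
#' double-tap recording artifacts; both are flagged out. The bounds are
#' inclusive: exactly `min_ms` or `max_ms` is kept. Flagged intervals stay in
#' the series (ordering preserved) for audit.
#'
#' @param series An `iti_series`.
#' @param min_ms Lower bound in ms (default 120).
#' @param max_ms Upper bound in ms (default 2000).
#' @return The series with updated flags.
#' @export
filter_itis <- function(series, min_ms = 120, max_ms = 2000) {
  if (min_ms >= max_ms) {
    stop("filter_itis(): min_ms must be < max_ms", call. = FALSE)
  }
  series$flag <- ifelse(series$interval_ms < min_ms, "too_short",
                 ifelse(series$interval_ms > max_ms, "too_long", "kept"))
  series
}
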