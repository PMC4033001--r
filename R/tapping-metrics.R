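#' Pool the inter-tap-interval series of several blocks
#'
#' Concatenates the interval series of blocks recorded within the same
#' session (for example the blocks tapped before and after a therapy
#' session) in chronological block order. Intervals never span block
#' boundaries: no interval is formed between the last tap of one block and
#' the first tap of the next.
#'
#' @param blocks A non-empty list of `iti_series` objects.
#' @return A single pooled `iti_series`.
#' @export
pool_session_blocks <- function(blocks) {
  if (!is.list(blocks) || length(blocks) == 0L) {
    stop("pool_session_blocks(): need at least one block", call. = FALSE)
  }
  if (!all(vapply(blocks, inherits, TRUE, what = "iti_series"))) {
    stop("pool_session_blocks(): all blocks must be iti_series", call. = FALSE)
  }
  pooled <- do.call(rbind, lapply(blocks, as.data.frame))
  iti_series(pooled$interval_ms, pooled$flag)
}

#' Tapping speed: median inter-tap interval
#'
#' Speed is the sample median of the kept intervals, in ms (even counts
#' average the central pair). Lower is faster.
#'
#' @param series An `iti_series`.
#' @return Median interval in ms, or `NA` if no intervals are kept.
#' @export
speed_median <- function(series) {
  iv <- kept_itis(series)
  if (length(iv) == 0L) return(NA_real_)
  stats::median(iv)
}

#' Tapping variability: trimmed coefficient of variation
#'
#' Computes, over the kept intervals of a block: (1) mean and sample SD;
#' (2) discards intervals more than 3 SD from the mean; (3) returns
#' `100 * SD(remaining) / mean(remaining)` in percent. The 3-SD trim is a
#' single pass. The denominator uses the post-trim mean, so SD and mean
#' describe the same remaining set (switchable via `denominator`).
#'
#' @param series An `iti_series`.
#' @param n_sd Trim bound in SD units (default 3).
#' @param denominator `"post_trim"` (default) or `"pre_trim"` mean.
#' @return CV in percent, or `NA` with fewer than 2 intervals after trimming.
#' @export
variability_cv <- function(series, n_sd = 3, denominator = c("post_trim", "pre_trim")) {
  denominator <- match.arg(denominator)
  iv <- kept_itis(series)
  if (length(iv) < 2L) return(NA_real_)
  m <- mean(iv)
  s <- stats::sd(iv)
  keep <- if (s > 0) abs(iv - m) <= n_sd * s else rep(TRUE, length(iv))
  iv2 <- iv[keep]
  if (length(iv2) < 2L) return(NA_real_)
  denom <- if (denominator == "post_trim") mean(iv2) else m
  100 * stats::sd(iv2) / denom
}

#' Summarize a tapping block or session
#'
#' Applies the physiological interval filter, then computes the speed
#' (median interval), variability (trimmed CV) and mean per-tap features.
#' Intervals are taken from the first tap for at most `window_s` seconds,
#' matching the task protocol (about 14 s for unpaced speed tapping, 60 s
#' paced).
#'
#' @param taps A `tap_events` data frame from [detect_taps()].
#' @param session_label Label carried into the summary.
#' @param window_s Analysis window from the first tap onset in s
#'   (default `Inf` = whole recording).
#' @param min_iti_ms,max_iti_ms Physiological interval bounds (ms).
#' @return A one-row `data.frame`: `session_label`, `n_taps`,
#'   `median_iti_ms`, `cv_percent`, `mean_peak_force_n`, `mean_dwell_ms`.
#' @export
summarize_tapping <- function(taps, session_label = "session",
                              window_s = Inf, min_iti_ms = 120,
                              max_iti_ms = 2000) {
  if (nrow(taps) > 0L && is.finite(window_s)) {
    taps <- taps[taps$onset_ms <= taps$onset_ms[1L] + window_s * 1000, ,
                 drop = FALSE]
  }
  series <- filter_itis(extract_itis(taps), min_iti_ms, max_iti_ms)
  data.frame(
    session_label = session_label,
    n_taps = nrow(taps),
    median_iti_ms = speed_median(series),
    cv_percent = variability_cv(series),
    mean_peak_force_n = if (nrow(taps)) mean(taps$peak_force_n) else NA_real_,
    mean_dwell_ms = if (nrow(taps)) mean(taps$dwell_ms) else NA_real_
  )
}
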