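#' Parameters for synthetic unpaced (speed) tapping traces
#'
#' Defaults emulate the recording conditions of the speed-tapping blocks:
#' a force-sensitive resistor sampled at 3 kHz, taps roughly every 300 ms
#' with ~10% interval variability, and the artifact types seen in patient
#' recordings — "soft" taps whose peak stays below the 0.05 N detection
#' threshold, spurious double-tap re-contacts within 120 ms, and pauses
#' longer than 2 s when the patient interrupts tapping.
#'
#' Inter-tap intervals are drawn log-normal, parameterized by arithmetic mean
#' and coefficient of variation: strictly positive and right-skewed like real
#' inter-tap intervals.
#'
#' @param mean_iti Mean inter-tap interval in ms.
#' @param iti_cv Coefficient of variation of the intervals (fraction).
#' @param peak_force Peak contact force in N.
#' @param dwell_ms Contact (dwell) duration in ms, rise to release.
#' @param pulse_rise_ms,pulse_fall_ms Linear rise/fall times of the force
#'   pulse in ms; must satisfy `pulse_rise_ms + pulse_fall_ms < dwell_ms`.
#' @param noise_sd Additive Gaussian sensor noise SD in N (clipped at 0 N:
#'   a resistive sensor cannot report negative force).
#' @param soft_tap_rate Fraction of taps with peak force drawn uniformly
#'   below the detection threshold.
#' @param double_tap_rate Fraction of taps followed by a brief spurious
#'   re-contact within 120 ms of the parent onset.
#' @param pause_rate Probability that any given interval is replaced by a
#'   pause longer than 2000 ms.
#' @param duration_s Recording duration in s.
#' @param sample_rate_hz Sample rate in Hz (default 3000).
#' @return An object of class `tap_gen_params`.
#' @export
tap_gen_params <- function(mean_iti = 300, iti_cv = 0.1, peak_force = 0.5,
                           dwell_ms = 100, pulse_rise_ms = 10,
                           pulse_fall_ms = 10, noise_sd = 0.005,
                           soft_tap_rate = 0, double_tap_rate = 0,
                           pause_rate = 0, duration_s = 14,
                           sample_rate_hz = 3000) {
  if (mean_iti <= 0) stop("parameter error: mean_iti must be > 0", call. = FALSE)
  if (peak_force <= 0) stop("parameter error: peak_force must be > 0", call. = FALSE)
  if (duration_s <= 0) stop("parameter error: duration_s must be > 0", call. = FALSE)
  if (sample_rate_hz <= 0) stop("parameter error: sample_rate_hz must be > 0", call. = FALSE)
  for (r in c(soft_tap_rate, double_tap_rate, pause_rate)) {
    if (r < 0 || r > 1) stop("parameter error: rates must be in [0, 1]", call. = FALSE)
  }
  if (iti_cv < 0) stop("parameter error: iti_cv must be >= 0", call. = FALSE)
  if (pulse_rise_ms + pulse_fall_ms >= dwell_ms) {
    stop("parameter error: rise + fall must be shorter than dwell", call. = FALSE)
  }
  structure(as.list(environment())[c(
    "mean_iti", "iti_cv", "peak_force", "dwell_ms", "pulse_rise_ms",
    "pulse_fall_ms", "noise_sd", "soft_tap_rate", "double_tap_rate",
    "pause_rate", "duration_s", "sample_rate_hz"
  )], class = "tap_gen_params")
}

#' Parameters for synthetic metronome-paced tapping traces
#'
#' Defaults emulate the paced thumb-to-index task: a metronome at 69 BPM
#' (1.15 Hz) for 60 s, with tap onsets scattered around the clicks by a
#' wrapped-normal asynchrony. Healthy and patient tappers alike tend to
#' anticipate the click, hence the negative default mean asynchrony.
#'
#' @param tempo_bpm Metronome tempo in beats per minute (default 69).
#' @param mean_asynchrony_ms Mean tap-click asynchrony in ms (negative =
#'   anticipation).
#' @param asynchrony_sd_ms SD of the asynchrony in ms (wrapped onto the
#'   click cycle).
#' @param duration_s Recording duration in s (default 60).
#' @param peak_force,dwell_ms,pulse_rise_ms,pulse_fall_ms,noise_sd,sample_rate_hz
#'   Pulse and noise fields as in [tap_gen_params()].
#' @return An object of class `paced_gen_params`.
#' @export
paced_gen_params <- function(tempo_bpm = 69, mean_asynchrony_ms = -30,
                             asynchrony_sd_ms = 40, duration_s = 60,
                             peak_force = 0.5, dwell_ms = 100,
                             pulse_rise_ms = 10, pulse_fall_ms = 10,
                             noise_sd = 0.005, sample_rate_hz = 3000) {
  if (tempo_bpm <= 0) stop("parameter error: tempo_bpm must be > 0", call. = FALSE)
  if (duration_s <= 0) stop("parameter error: duration_s must be > 0", call. = FALSE)
  if (asynchrony_sd_ms < 0) stop("parameter error: asynchrony_sd_ms must be >= 0", call. = FALSE)
  if (peak_force <= 0) stop("parameter error: peak_force must be > 0", call. = FALSE)
  if (pulse_rise_ms + pulse_fall_ms >= dwell_ms) {
    stop("parameter error: rise + fall must be shorter than dwell", call. = FALSE)
  }
  structure(as.list(environment())[c(
    "tempo_bpm", "mean_asynchrony_ms", "asynchrony_sd_ms", "duration_s",
    "peak_force", "dwell_ms", "pulse_rise_ms", "pulse_fall_ms", "noise_sd",
    "sample_rate_hz"
  )], class = "paced_gen_params")
}

# force contribution of one piecewise-linear pulse at times t_ms after contact
pulse_force <- function(t_ms, peak, dwell, rise, fall) {
  f <- numeric(length(t_ms))
  up <- t_ms >= 0 & t_ms < rise
  flat <- t_ms >= rise & t_ms <= dwell - fall
  down <- t_ms > dwell - fall & t_ms <= dwell
  f[up] <- peak * t_ms[up] / rise
  f[flat] <- peak
  f[down] <- peak * (dwell - t_ms[down]) / fall
  f
}

# Render pulses onto a sample grid. contacts/peaks/dwells in ms / N.
render_pulses <- function(n_samples, rate_hz, contacts_ms, peaks, dwells,
                          rise, fall) {
  x <- numeric(n_samples)
  ms_per_sample <- 1000 / rate_hz
  for (j in seq_along(contacts_ms)) {
    i0 <- max(1L, floor(contacts_ms[j] / ms_per_sample) + 1L)
    i1 <- min(n_samples, ceiling((contacts_ms[j] + dwells[j]) / ms_per_sample) + 1L)
    if (i0 > i1) next
    idx <- i0:i1
    t_rel <- (idx - 1L) * ms_per_sample - contacts_ms[j]
    seg <- pulse_force(t_rel, peaks[j], dwells[j], rise, fall)
    x[idx] <- pmax(x[idx], seg)
  }
  x
}

# Landmark ground truth: what the landmarking convention (threshold crossing
# plus the 40/75 ms refractory rules) assigns to each generated contact, read
# off the noiseless smoothed trace. Implemented as a walk over the
# supra-threshold runs -- a different route than detect_taps()'s sample-level
# forward scan, so the two can cross-validate each other. Contacts whose
# pulse never crosses threshold (soft taps) and contacts absorbed into the
# preceding contact's event (merged double taps, refractory-skipped runs)
# get NA landmarks.
landmark_ground_truth <- function(clean, rate_hz, contacts_ms, dwells,
                                  threshold_n, smooth_window,
                                  min_offset_after_onset_ms = 40,
                                  min_onset_after_offset_ms = 75) {
  trace <- force_trace(clean, rate_hz, units = "newton")
  sm <- smooth_bartlett(trace, smooth_window)$samples
  above <- sm > threshold_n
  n <- length(sm)
  ms_per_sample <- 1000 / rate_hz
  off_ref <- ceiling(min_offset_after_onset_ms / ms_per_sample)
  on_ref <- ceiling(min_onset_after_offset_ms / ms_per_sample)
  d <- diff(c(FALSE, above, FALSE))
  run_start <- which(d == 1L)
  run_end <- which(d == -1L) - 1L

  ev_onset <- ev_offset <- integer(0)
  pos <- 1L
  for (r in seq_along(run_start)) {
    if (run_end[r] < pos) next # run inside the previous event or its refractory
    onset <- max(run_start[r], pos)
    from <- onset + off_ref
    if (from > n) break
    # offset: first sub-threshold sample at or after `from` (possibly
    # bridging later runs if they start within the offset refractory)
    q <- which(run_start <= from & run_end >= from)
    offset <- if (length(q) == 1L) run_end[q] + 1L else from
    while (offset <= n && above[offset]) { # bridged into yet another run
      q <- which(run_start <= offset & run_end >= offset)
      offset <- run_end[q] + 1L
    }
    if (offset > n) break # trailing onset without qualifying offset
    ev_onset <- c(ev_onset, onset)
    ev_offset <- c(ev_offset, offset)
    pos <- offset + on_ref
  }

  # match events to contacts in time order; the smoothing kernel can move a
  # landmark by up to half the window, hence the matching margin
  margin <- (smooth_window / 2 + 1) * ms_per_sample
  onset_ms <- rep(NA_real_, length(contacts_ms))
  offset_ms <- rep(NA_real_, length(contacts_ms))
  j <- 1L
  for (e in seq_along(ev_onset)) {
    t_on <- (ev_onset[e] - 1L) * ms_per_sample
    t_off <- (ev_offset[e] - 1L) * ms_per_sample
    while (j <= length(contacts_ms) &&
           contacts_ms[j] + dwells[j] + margin < t_on) {
      j <- j + 1L # contact left no recoverable event
    }
    if (j <= length(contacts_ms) && contacts_ms[j] - margin <= t_off) {
      onset_ms[j] <- t_on
      offset_ms[j] <- t_off
      j <- j + 1L
    }
  }
  list(onset_ms = onset_ms, offset_ms = offset_ms)
}

#' Generate an unpaced speed-tapping force trace with ground truth
#'
#' Builds a zero-based force trace of `duration_s * sample_rate_hz` samples in
#' Newtons containing every generated contact — including sub-threshold soft
#' taps, double-tap re-contacts and pauses — and returns exact ground truth
#' for each contact. The ground truth carries both the physical contact time
#' (`contact_ms`, used for interval statistics) and the landmark that the
#' full landmarking convention (trim, smooth, 0.05 N threshold, 40/75 ms
#' refractory rules) assigns to the contact (`onset_ms`/`offset_ms`, read off
#' the noiseless smoothed trace by a run-level walk independent of
#' [detect_taps()]'s sample-level scan; `NA` for contacts that never cross
#' threshold or that merge into the preceding contact's event).
#'
#' @param params A [tap_gen_params()].
#' @param seed Integer seed; identical `(params, seed)` give bit-identical
#'   output.
#' @param threshold_n Detection threshold convention used for the landmark
#'   ground truth (default 0.05 N).
#' @param smooth_window Bartlett window used for the landmark ground truth
#'   (default 160 samples).
#' @return A list with elements `trace` (a [force_trace()] in Newtons) and
#'   `truth` (data frame: `contact_ms`, `release_ms`, `onset_ms`, `offset_ms`,
#'   `peak_force_n`, `is_soft`, `is_double`, `after_pause`).
#' @export
generate_unpaced_trace <- function(params = tap_gen_params(), seed = 1L,
                                   threshold_n = 0.05, smooth_window = 160L) {
  stopifnot(inherits(params, "tap_gen_params"))
  set.seed(as.integer(seed))
  p <- params
  total_ms <- p$duration_s * 1000
  margin_ms <- 700 # clear of the trimmed 0.5 s edges plus the smoothing span
  if (total_ms <= 2 * margin_ms + p$dwell_ms) {
    stop("parameter error: duration_s too short for the edge margins", call. = FALSE)
  }

  # contact times: log-normal intervals with the requested mean and CV,
  # occasionally replaced by a pause
  sdlog <- sqrt(log(1 + p$iti_cv^2))
  meanlog <- log(p$mean_iti) - sdlog^2 / 2
  contacts <- numeric(0)
  after_pause <- logical(0)
  t <- margin_ms
  while (t + p$dwell_ms <= total_ms - margin_ms) {
    contacts <- c(contacts, t)
    paused <- p$pause_rate > 0 && stats::runif(1) < p$pause_rate
    after_pause <- c(after_pause, paused)
    iti <- if (paused) {
      stats::runif(1, 2200, 3500)
    } else if (p$iti_cv == 0) {
      p$mean_iti
    } else {
      stats::rlnorm(1, meanlog, sdlog)
    }
    t <- t + iti
  }
  after_pause <- c(FALSE, after_pause[-length(after_pause)])
  n_taps <- length(contacts)
  if (n_taps == 0L) stop("parameter error: no taps fit in the trace", call. = FALSE)

  is_soft <- stats::runif(n_taps) < p$soft_tap_rate
  peaks <- rep(p$peak_force, n_taps)
  peaks[is_soft] <- stats::runif(sum(is_soft), 0, threshold_n)
  dwells <- rep(p$dwell_ms, n_taps)
  is_double <- rep(FALSE, n_taps)

  # spurious re-contacts: a brief extra pulse shortly after the parent release
  dbl_parent <- which(stats::runif(n_taps) < p$double_tap_rate & !is_soft)
  if (length(dbl_parent) > 0L) {
    dbl_dwell <- 30
    gap <- stats::runif(length(dbl_parent), 5, 15)
    dbl_contacts <- contacts[dbl_parent] + dwells[dbl_parent] + gap
    contacts <- c(contacts, dbl_contacts)
    peaks <- c(peaks, 0.6 * peaks[dbl_parent])
    dwells <- c(dwells, rep(dbl_dwell, length(dbl_parent)))
    is_soft <- c(is_soft, rep(FALSE, length(dbl_parent)))
    is_double <- c(is_double, rep(TRUE, length(dbl_parent)))
    after_pause <- c(after_pause, rep(FALSE, length(dbl_parent)))
    ord <- order(contacts)
    contacts <- contacts[ord]; peaks <- peaks[ord]; dwells <- dwells[ord]
    is_soft <- is_soft[ord]; is_double <- is_double[ord]
    after_pause <- after_pause[ord]
  }

  n_samples <- round(p$duration_s * p$sample_rate_hz)
  clean <- render_pulses(n_samples, p$sample_rate_hz, contacts, peaks, dwells,
                         p$pulse_rise_ms, p$pulse_fall_ms)
  lm <- landmark_ground_truth(clean, p$sample_rate_hz, contacts, dwells,
                              threshold_n, smooth_window)
  samples <- clean
  if (p$noise_sd > 0) {
    samples <- pmax(0, samples + stats::rnorm(n_samples, 0, p$noise_sd))
  }
  truth <- data.frame(
    contact_ms = contacts,
    release_ms = contacts + dwells,
    onset_ms = lm$onset_ms,
    offset_ms = lm$offset_ms,
    peak_force_n = peaks,
    is_soft = is_soft,
    is_double = is_double,
    after_pause = after_pause
  )
  list(
    trace = force_trace(samples, p$sample_rate_hz, units = "newton",
                        recording_id = sprintf("synthetic-unpaced-%d", seed)),
    truth = truth
  )
}

#' Generate a metronome-paced tapping trace with schedule and ground truth
#'
#' Clicks are spaced exactly `60000 / tempo_bpm` ms apart; each tap's contact
#' time is its click plus an asynchrony drawn from a normal distribution
#' wrapped onto the click cycle. Trace rendering and landmark ground truth
#' follow [generate_unpaced_trace()].
#'
#' @param params A [paced_gen_params()].
#' @param seed Integer seed.
#' @inheritParams generate_unpaced_trace
#' @return A list with elements `trace`, `schedule` (a
#'   [metronome_schedule()]) and `truth` (data frame with `click_ms`,
#'   `asynchrony_ms`, `contact_ms`, `release_ms`, `onset_ms`, `offset_ms`,
#'   `peak_force_n`).
#' @export
generate_paced_trace <- function(params = paced_gen_params(), seed = 1L,
                                 threshold_n = 0.05, smooth_window = 160L) {
  stopifnot(inherits(params, "paced_gen_params"))
  set.seed(as.integer(seed))
  p <- params
  total_ms <- p$duration_s * 1000
  interval <- 60000 / p$tempo_bpm
  margin_ms <- 1000
  clicks <- seq(margin_ms, total_ms - margin_ms - p$dwell_ms, by = interval)
  if (length(clicks) < 1L) {
    stop("parameter error: duration_s too short for any click", call. = FALSE)
  }
  asyn <- stats::rnorm(length(clicks), p$mean_asynchrony_ms, p$asynchrony_sd_ms)
  # wrap onto the click cycle: (-interval/2, interval/2]
  asyn <- asyn - interval * floor(asyn / interval + 0.5)
  contacts <- clicks + asyn
  ord <- order(contacts)
  n_samples <- round(p$duration_s * p$sample_rate_hz)
  dwells <- rep(p$dwell_ms, length(contacts))
  peaks <- rep(p$peak_force, length(contacts))
  clean <- render_pulses(n_samples, p$sample_rate_hz, contacts[ord], peaks,
                         dwells, p$pulse_rise_ms, p$pulse_fall_ms)
  lm <- landmark_ground_truth(clean, p$sample_rate_hz, contacts[ord], dwells,
                              threshold_n, smooth_window)
  samples <- clean
  if (p$noise_sd > 0) {
    samples <- pmax(0, samples + stats::rnorm(n_samples, 0, p$noise_sd))
  }
  truth <- data.frame(
    click_ms = clicks[ord],
    asynchrony_ms = asyn[ord],
    contact_ms = contacts[ord],
    release_ms = contacts[ord] + p$dwell_ms,
    onset_ms = lm$onset_ms,
    offset_ms = lm$offset_ms,
    peak_force_n = peaks
  )
  list(
    trace = force_trace(samples, p$sample_rate_hz, units = "newton",
                        recording_id = sprintf("synthetic-paced-%d", seed)),
    schedule = metronome_schedule(p$tempo_bpm, clicks),
    truth = truth
  )
}

#' Parameters for a synthetic two-group rehabilitation cohort
#'
#' Defaults emulate the structure of a 28-patient early-rehabilitation
#' cohort split into two therapy groups ("together" vs "in-turn"): ages
#' around the mid-sixties, Barthel index near 48, nine-hole pegboard times
#' with a large between-patient spread, a therapy-related pegboard
#' improvement shared by both groups, mood-questionnaire shifts (reduced
#' depression/anxiety and fatigue), and a gentle upward trend in the
#' session-by-session faces-scale mood ratings.
#'
#' @param n_per_group Patients per group (>= 2; default 14).
#' @param pegboard_pre_mean,pegboard_pre_sd Pre-therapy pegboard time, s.
#' @param pegboard_improvement_mean Named length-2 numeric (together,
#'   in_turn): mean POST minus PRE change in s (negative = faster after
#'   therapy).
#' @param pegboard_improvement_sd SD of the change in s (common to groups).
#' @param poms_shift Named numeric: mean PRE to POST change of each POMS
#'   subscale sum (depression_anxiety, fatigue, vigor, hostility), points.
#' @param faces_trend Named length-2 numeric (together, in_turn): mean
#'   ordinal steps per session in the faces-scale self ratings.
#' @param age_mean,age_sd Age distribution in years (truncated to 30-75).
#' @param p_female Probability that a patient is female.
#' @param barthel_mean,barthel_sd Barthel index at PRE.
#' @param seed Integer seed.
#' @return An object of class `cohort_gen_params`.
#' @export
cohort_gen_params <- function(n_per_group = 14,
                              pegboard_pre_mean = 57.5, pegboard_pre_sd = 34.8,
                              pegboard_improvement_mean = c(together = -10.5,
                                                            in_turn = -10.5),
                              pegboard_improvement_sd = 12,
                              poms_shift = c(depression_anxiety = -4,
                                             fatigue = -3, vigor = 0.5,
                                             hostility = -2),
                              faces_trend = c(together = 0.1, in_turn = 0.1),
                              age_mean = 66, age_sd = 11, p_female = 0.57,
                              barthel_mean = 48.5, barthel_sd = 13,
                              seed = 1L) {
  if (n_per_group < 2) stop("parameter error: n_per_group must be >= 2", call. = FALSE)
  for (s in c(pegboard_pre_sd, pegboard_improvement_sd, age_sd, barthel_sd)) {
    if (s < 0) stop("parameter error: sd fields must be >= 0", call. = FALSE)
  }
  stopifnot(length(pegboard_improvement_mean) == 2L, length(faces_trend) == 2L,
            all(c("depression_anxiety", "fatigue", "vigor", "hostility") %in%
                  names(poms_shift)))
  structure(as.list(environment())[c(
    "n_per_group", "pegboard_pre_mean", "pegboard_pre_sd",
    "pegboard_improvement_mean", "pegboard_improvement_sd", "poms_shift",
    "faces_trend", "age_mean", "age_sd", "p_female", "barthel_mean",
    "barthel_sd", "seed"
  )], class = "cohort_gen_params")
}

clamp_round <- function(x, lo, hi) pmin(pmax(round(x), lo), hi)

# lower-truncated normal via the inverse CDF (one uniform per draw keeps the
# RNG stream length fixed, so seeds stay reproducible)
rtnorm_lower <- function(n, mean, sd, lower) {
  if (sd == 0) return(pmax(rep(mean, n), lower))
  lo <- stats::pnorm((lower - mean) / sd)
  mean + sd * stats::qnorm(stats::runif(n, lo, 1))
}

#' Generate a synthetic two-group cohort
#'
#' Produces patient-level covariates and outcomes for `2 * n_per_group`
#' patients: PRE/POST nine-hole pegboard times, 35-item POMS ratings at PRE
#' and POST, and faces-scale self ratings at 12 time points (PRE, therapy
#' sessions 1-10, POST). Reproducible from `params$seed`.
#'
#' @param params A [cohort_gen_params()].
#' @return An object of class `cohort`: a list with data frames `patients`
#'   (one row per patient), `poms` (one row per patient and timepoint, item
#'   columns `item_01` .. `item_35`) and `faces` (long: patient, time index
#'   1-12, label, rating).
#' @export
generate_cohort <- function(params = cohort_gen_params()) {
  stopifnot(inherits(params, "cohort_gen_params"))
  p <- params
  set.seed(as.integer(p$seed))
  n <- 2L * p$n_per_group
  groups <- rep(c("together", "in_turn"), each = p$n_per_group)
  age <- clamp_round(stats::rnorm(n, p$age_mean, p$age_sd), 30, 75)
  sex <- ifelse(stats::runif(n) < p$p_female, "F", "M")
  barthel_pre <- clamp_round(stats::rnorm(n, p$barthel_mean, p$barthel_sd), 0, 100)
  barthel_post <- clamp_round(barthel_pre + stats::rnorm(n, 22, 8), 0, 100)
  days <- clamp_round(stats::rlnorm(n, log(38), 0.6), 5, 150)
  peg_pre <- rtnorm_lower(n, p$pegboard_pre_mean, p$pegboard_pre_sd, 10)
  impr_mean <- p$pegboard_improvement_mean[ifelse(groups == "together", 1L, 2L)]
  peg_post <- rtnorm_lower(n, peg_pre + impr_mean, p$pegboard_improvement_sd, 5)

  patients <- data.frame(
    patient_id = sprintf("P%02d", seq_len(n)),
    group = groups,
    age = age,
    sex = sex,
    affected_hand = ifelse(stats::runif(n) < 0.6, "R", "L"),
    days_since_stroke = days,
    barthel_pre = barthel_pre,
    barthel_post = barthel_post,
    pegboard_pre_s = peg_pre,
    pegboard_post_s = peg_post
  )

  # POMS: per-item latent mood with a per-subscale PRE->POST shift spread
  # evenly over the subscale's items
  mapping <- poms_mapping()
  shift_per_item <- numeric(35)
  for (sub in names(p$poms_shift)) {
    items <- mapping == sub
    shift_per_item[items] <- p$poms_shift[[sub]] / sum(items)
  }
  latent <- stats::rnorm(n, 2.5, 0.4)
  mu <- rbind(matrix(latent, n, 35),
              matrix(latent, n, 35) + matrix(shift_per_item, n, 35, byrow = TRUE))
  ratings <- clamp_round(mu + stats::rnorm(2L * n * 35, 0, 0.8), 1, 5)
  colnames(ratings) <- sprintf("item_%02d", 1:35)
  poms <- cbind(
    data.frame(patient_id = rep(patients$patient_id, 2L),
               timepoint = rep(c("PRE", "POST"), each = n)),
    as.data.frame(ratings)
  )
  poms <- poms[order(match(poms$patient_id, patients$patient_id),
                     match(poms$timepoint, c("PRE", "POST"))), ]
  rownames(poms) <- NULL

  # faces scale: 12 time points (PRE, sessions 1-10, POST), 1..7, higher =
  # happier, linear trend per group plus ordinal noise
  labels <- c("PRE", sprintf("S%02d", 1:10), "POST")
  trend <- p$faces_trend[ifelse(groups == "together", 1L, 2L)]
  base <- stats::rnorm(n, 3.5, 0.9)
  vals <- clamp_round(
    rep(base, each = 12L) + rep(trend, each = 12L) * rep(0:11, n) +
      stats::rnorm(12L * n, 0, 0.8), 1, 7)
  faces <- data.frame(patient_id = rep(patients$patient_id, each = 12L),
                      time_index = rep(1:12, n),
                      label = rep(labels, n),
                      rating = vals)

  structure(list(patients = patients, poms = poms, faces = faces,
                 params = p),
            class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("<cohort: %d patients (%s), POMS %d rows, faces %d rows>\n",
              nrow(x$patients),
              paste(table(x$patients$group), collapse = " + "),
              nrow(x$poms), nrow(x$faces)))
  invisible(x)
}

#' Write a cohort to plain-text CSV files
#'
#' Writes `patients.csv` (one row per patient), `poms.csv` (wide, 35 item
#' columns) and `faces.csv` (long) into `dir`.
#'
#' @param cohort A `cohort` object.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(cohort$patients, file.path(dir, "patients.csv"),
                   row.names = FALSE)
  utils::write.csv(cohort$poms, file.path(dir, "poms.csv"), row.names = FALSE)
  utils::write.csv(cohort$faces, file.path(dir, "faces.csv"), row.names = FALSE)
  invisible(dir)
}
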