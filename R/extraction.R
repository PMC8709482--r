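# Evoked-response extraction: epoching, peak-to-peak measurement with
# artifact blanking, the 2.5 SD outlier rule, recruitment curves, and
# force-onset reaction times.

sample_index <- function(t_s, fs) round(t_s * fs) + 1L

#' Extract an epoch from one channel
#'
#' Returns the samples in the half-open window `[t0 + window[1], t0 +
#' window[2])`, with nearest-sample rounding of the endpoints.
#'
#' @param session A [semp_session()].
#' @param channel Channel name.
#' @param t0_s Reference time (s).
#' @param window Length-2 numeric `(start_s, end_s)` relative to `t0_s`.
#' @return Numeric vector of samples.
#' @export
extract_epoch <- function(session, channel, t0_s, window) {
  fs <- session$sampling_rate_hz
  x <- session$signals[[channel]]
  if (is.null(x)) stop("no such channel: ", channel, call. = FALSE)
  n <- round((window[2] - window[1]) * fs)
  if (n <= 0) stop("zero-length epoch window", call. = FALSE)
  i0 <- sample_index(t0_s + window[1], fs)
  ii <- i0 + seq_len(n) - 1L
  if (i0 < 1L || max(ii) > length(x)) {
    stop("epoch window outside recording", call. = FALSE)
  }
  x[ii]
}

#' Peak-to-peak amplitude of an epoch
#'
#' @param epoch Non-empty numeric vector (NAs, e.g. blanked samples, are
#'   dropped).
#' @return `max(epoch) - min(epoch)`, always >= 0.
#' @export
peak_to_peak <- function(epoch) {
  epoch <- epoch[!is.na(epoch)]
  if (length(epoch) == 0) stop("empty epoch", call. = FALSE)
  max(epoch) - min(epoch)
}

#' Response-measurement settings
#'
#' Windows are relative to each stimulation pulse. The evoked response is
#' measured 5-45 ms post-pulse (so the R1 window ends before the second pulse
#' of a 50 ms doublet) and samples within 0-3 ms of any pulse are blanked to
#' remove the stimulus artifact. The response floor used for flagging and the
#' motor threshold is 0.02 mV peak-to-peak.
#'
#' @param response_window_s `(start, end)` seconds post-pulse.
#' @param blank_window_s `(start, end)` seconds post-pulse to blank.
#' @param floor_mv Response floor (mV).
#' @return A list of settings.
#' @export
measure_settings <- function(response_window_s = c(0.005, 0.045),
                             blank_window_s = c(0, 0.003),
                             floor_mv = 0.02) {
  list(response_window_s = response_window_s,
       blank_window_s = blank_window_s,
       floor_mv = floor_mv)
}

blank_pulse_samples <- function(epoch, epoch_start_s, fs, pulse_times_s, blank) {
  t <- epoch_start_s + (seq_along(epoch) - 1L) / fs
  for (tp in pulse_times_s) {
    epoch[t >= tp + blank[1] - 1e-12 & t < tp + blank[2] - 1e-12] <- NA_real_
  }
  epoch
}

#' Measure R1 and R2 of one stimulation doublet
#'
#' Extracts the post-pulse response windows for both pulses of a doublet on
#' one muscle channel, blanks stimulus-artifact samples, and returns the
#' peak-to-peak amplitudes with quality flags: `R1_BELOW_FLOOR` when R1 falls
#' below the response floor and `R2_EXCEEDS_R1` when R2 > R1 (suggesting
#' volitional contamination).
#'
#' @param session A [semp_session()].
#' @param trial One row of [event_trials()] with two pulse times.
#' @param muscle EMG channel name.
#' @param settings A [measure_settings()].
#' @return One-row data frame: trial keys, `muscle`, `r1_pp`, `r2_pp`,
#'   `r1_below_floor`, `r2_exceeds_r1`, plus window bounds.
#' @export
measure_doublet <- function(session, trial, muscle,
                            settings = measure_settings()) {
  if (is.na(trial$pulse1_s) || is.na(trial$pulse2_s)) {
    stop("trial has no stimulation doublet", call. = FALSE)
  }
  fs <- session$sampling_rate_hz
  win <- settings$response_window_s
  pulses <- c(trial$pulse1_s, trial$pulse2_s)
  if (trial$pulse1_s + win[2] > trial$pulse2_s + settings$blank_window_s[1]) {
    stop("R1 response window collides with the second pulse", call. = FALSE)
  }
  pp <- vapply(pulses, function(tp) {
    ep <- extract_epoch(session, muscle, tp, win)
    ep <- blank_pulse_samples(ep, tp + win[1], fs, pulses, settings$blank_window_s)
    peak_to_peak(ep)
  }, numeric(1))
  data.frame(
    trial_id = trial$trial_id, movement = trial$movement,
    condition = trial$condition, phase = trial$phase, cti_ms = trial$cti_ms,
    muscle = muscle, r1_pp = pp[1], r2_pp = pp[2],
    r1_below_floor = pp[1] < settings$floor_mv,
    r2_exceeds_r1 = pp[2] > pp[1],
    r1_win_start_s = pulses[1] + win[1], r1_win_end_s = pulses[1] + win[2],
    r2_win_start_s = pulses[2] + win[1], r2_win_end_s = pulses[2] + win[2]
  )
}

#' Measure every stimulation doublet of a session
#'
#' Applies [measure_doublet()] to all stimulated trials and all EMG channels
#' present in the session.
#'
#' @param session A [semp_session()].
#' @param settings A [measure_settings()].
#' @return Doublet table: one row per trial x muscle.
#' @export
measure_session <- function(session, settings = measure_settings()) {
  trials <- event_trials(session$events)
  stim <- trials[!is.na(trials$pulse1_s), , drop = FALSE]
  muscles <- intersect(EMG_CHANNELS, names(session$signals))
  rows <- vector("list", nrow(stim) * length(muscles))
  k <- 0L
  for (i in seq_len(nrow(stim))) {
    for (mus in muscles) {
      k <- k + 1L
      rows[[k]] <- measure_doublet(session, stim[i, ], mus, settings)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Outlier inclusion mask (2.5 SD rule)
#'
#' A value is excluded when it lies strictly more than `k` sample standard
#' deviations from the mean, both computed over all submitted values
#' (including the candidate). Single pass: the rule is not re-applied to the
#' retained set. With fewer than 3 values no exclusion is performed.
#'
#' @param values Numeric vector.
#' @param k SD multiple (default 2.5).
#' @return Logical mask, `TRUE` = keep.
#' @export
exclude_outliers <- function(values, k = 2.5) {
  n <- length(values)
  if (n < 3) {
    if (n > 0) warning("fewer than 3 values: no outlier exclusion performed")
    return(rep(TRUE, n))
  }
  s <- stats::sd(values)
  if (!is.finite(s) || s == 0) return(rep(TRUE, n))
  abs(values - mean(values)) <= k * s
}

#' Build a recruitment curve
#'
#' Mean R1 amplitude per stimulation intensity.
#'
#' @param doublets Data frame with `intensity_mA` and `r1_pp`.
#' @return Object of class `semp_recruitment`: data frame `intensity_mA`
#'   (strictly increasing), `mean_r1_pp`, `n`.
#' @export
build_recruitment_curve <- function(doublets) {
  if (length(unique(doublets$intensity_mA)) < 2) {
    stop("need at least 2 intensity levels", call. = FALSE)
  }
  sp <- split(doublets$r1_pp, doublets$intensity_mA)
  out <- data.frame(
    intensity_mA = as.numeric(names(sp)),
    mean_r1_pp = vapply(sp, mean, numeric(1)),
    n = lengths(sp)
  )
  out <- out[order(out$intensity_mA), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("semp_recruitment", "data.frame"))
}

#' Estimate the motor threshold from a recruitment curve
#'
#' The motor threshold is the lowest sampled intensity whose mean response
#' reaches the response floor with all higher sampled intensities also at or
#' above the floor (a sustained crossing, robust to isolated noise bumps).
#'
#' @param curve A [build_recruitment_curve()] result.
#' @param floor_mv Response floor (mV), default 0.02.
#' @return Threshold intensity in mA, or `NA` if the floor is never reached.
#' @export
estimate_threshold <- function(curve, floor_mv = 0.02) {
  if (any(diff(curve$intensity_mA) <= 0)) {
    stop("recruitment intensities must be strictly increasing", call. = FALSE)
  }
  above <- curve$mean_r1_pp >= floor_mv
  if (!any(above)) return(NA_real_)
  # last run of consecutive TRUEs reaching the top of the curve
  idx <- which(!above)
  start <- if (length(idx) == 0) 1L else max(idx) + 1L
  if (start > nrow(curve)) return(NA_real_)
  curve$intensity_mA[start]
}

#' Detect force onset and reaction time
#'
#' Onset is the first time after the cue at which the force exceeds the
#' pre-cue baseline mean by `k` baseline SDs and stays above that threshold
#' for at least `hold_ms`.
#'
#' @param force Force trace (numeric vector).
#' @param cue_time_s Cue time (s).
#' @param sampling_rate_hz Sampling rate.
#' @param baseline_window_s Length of the pre-cue baseline window (s).
#' @param k Threshold in baseline SDs above the baseline mean.
#' @param hold_ms Minimum supra-threshold duration (ms).
#' @param max_rt_s Search horizon after the cue (s).
#' @return Reaction time in ms, or `NA` if no sustained crossing occurs.
#' @export
detect_force_onset <- function(force, cue_time_s, sampling_rate_hz,
                               baseline_window_s = 0.5, k = 3,
                               hold_ms = 25, max_rt_s = 1) {
  fs <- sampling_rate_hz
  i_cue <- sample_index(cue_time_s, fs)
  b0 <- sample_index(cue_time_s - baseline_window_s, fs)
  if (b0 < 1L || b0 >= i_cue) stop("baseline window empty or before recording start", call. = FALSE)
  baseline <- force[b0:(i_cue - 1L)]
  thr <- mean(baseline) + k * stats::sd(baseline)
  i_end <- min(length(force), i_cue + round(max_rt_s * fs))
  seg <- force[i_cue:i_end]
  above <- seg > thr
  n_hold <- max(1L, round(hold_ms / 1000 * fs))
  if (length(seg) < n_hold) return(NA_real_)
  # sustained crossing: n_hold consecutive supra-threshold samples
  run <- stats::filter(as.numeric(above), rep(1, n_hold), sides = 1)
  hit <- which(run == n_hold)
  if (length(hit) == 0) return(NA_real_)
  onset_idx <- hit[1] - n_hold + 1L # first sample of the sustained run
  (onset_idx - 1L) / fs * 1000
}

#' Reaction times of a session's baseline block
#'
#' Applies [detect_force_onset()] to every reaction-time trial of a session.
#'
#' @param session A [semp_session()].
#' @param ... Passed to [detect_force_onset()].
#' @return Data frame `trial_id`, `movement`, `rt_ms`.
#' @export
measure_reaction_times <- function(session, ...) {
  trials <- event_trials(session$events)
  rt_tr <- trials[trials$phase == "rt_baseline", , drop = FALSE]
  rt <- vapply(seq_len(nrow(rt_tr)), function(i) {
    detect_force_onset(session$signals$force, rt_tr$cue_time_s[i],
                       session$sampling_rate_hz, ...)
  }, numeric(1))
  data.frame(trial_id = rt_tr$trial_id, movement = rt_tr$movement, rt_ms = rt)
}
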