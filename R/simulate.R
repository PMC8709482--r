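# Synthetic-session generator: draws the trial-level ground truth (R1/R2
# amplitudes, reaction times) and optionally renders it into multi-channel
# EMG + force signals with band-limited noise and stimulus artifacts.

rlnorm_mean <- function(n, mean, cv) {
  # lognormal with E[X] = mean and coefficient of variation cv
  if (cv == 0) return(rep(mean, length.out = n))
  sdlog <- sqrt(log1p(cv^2))
  stats::rlnorm(n, meanlog = log(mean) - sdlog^2 / 2, sdlog = sdlog)
}

#' Draw ground-truth doublet amplitudes for scheduled trials
#'
#' For every stimulated trial and every simulated muscle, draws the true R1
#' peak-to-peak amplitude as `base x participant_scale x modulation x eps1`
#' and the true R2 as `R1 x depression x eps2`, where `eps1`, `eps2` are
#' independent lognormal factors with mean 1 and CV `amplitude_cv`. Coupling
#' R2 to the realized R1 keeps the expected per-pair R2/R1 ratio equal to the
#' depression level while preserving `E[R2] = E[R1] x depression`.
#' Control doublets always have modulation 1; their depression is looked up
#' under `condition = "control"`.
#'
#' @param trials Trial table from [event_trials()] (rows without pulses are
#'   ignored).
#' @param em An [effect_model()].
#' @param muscles EMG channels to draw.
#' @param participant_scale Multiplicative participant-level amplitude scale.
#' @return Data frame: trial keys plus `muscle`, `r1_true`, `r2_true`,
#'   `contaminated`. Draws come from the current RNG stream.
#' @export
draw_doublet_amplitudes <- function(trials, em, muscles = EMG_CHANNELS,
                                    participant_scale = 1) {
  st <- trials[!is.na(trials$pulse1_s), , drop = FALSE]
  n_tr <- nrow(st)
  if (n_tr == 0) stop("no stimulated trials to draw", call. = FALSE)

  base <- em$base_amplitude_mv
  if (is.null(names(base))) base <- stats::setNames(rep_len(base, length(muscles)), muscles)

  contaminated <- st$phase %in% c("conditioned", "isometric") &
    stats::runif(n_tr) < em$contamination_prob

  grid <- expand.grid(row = seq_len(n_tr), muscle = muscles,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  gph <- st$phase[grid$row]
  cond_eff <- ifelse(gph %in% c("control_pre", "control_post"),
                     "control", st$condition[grid$row])
  cti_eff <- ifelse(gph == "conditioned", st$cti_ms[grid$row], NA_real_)

  key <- paste(grid$muscle, st$movement[grid$row], cond_eff, cti_eff, sep = "|")
  uk <- !duplicated(key)
  f_map <- stats::setNames(mapply(function(mus, mov, cnd, cti) {
    if (cnd == "control") 1
    else lookup_effect(em$modulation, mus, mov, cnd, cti, default = 1)
  }, grid$muscle[uk], st$movement[grid$row][uk], cond_eff[uk], cti_eff[uk]), key[uk])
  d_map <- stats::setNames(mapply(function(mus, mov, cnd, cti) {
    lookup_effect(em$depression, mus, mov, cnd, cti,
                  default = if (is.data.frame(em$depression)) 0.2 else em$depression)
  }, grid$muscle[uk], st$movement[grid$row][uk], cond_eff[uk], cti_eff[uk]), key[uk])

  m1 <- base[grid$muscle] * participant_scale * unname(f_map[key])
  n <- length(m1)
  r1 <- m1 * rlnorm_mean(n, 1, em$amplitude_cv)
  r2 <- r1 * unname(d_map[key]) * rlnorm_mean(n, 1, em$amplitude_cv)

  out <- data.frame(
    trial_id = st$trial_id[grid$row],
    movement = st$movement[grid$row],
    condition = st$condition[grid$row],
    phase = gph,
    cti_ms = st$cti_ms[grid$row],
    muscle = grid$muscle,
    r1_true = r1,
    r2_true = r2,
    contaminated = contaminated[grid$row]
  )
  out[order(out$trial_id, match(out$muscle, muscles)), , drop = FALSE]
}

draw_rt_ms <- function(n, mean_ms, sd_ms) {
  # normal truncated at 0 by redrawing
  rt <- stats::rnorm(n, mean_ms, sd_ms)
  while (any(bad <- rt <= 0)) rt[bad] <- stats::rnorm(sum(bad), mean_ms, sd_ms)
  rt
}

#' Band-limited Gaussian noise
#'
#' White Gaussian noise filtered to the surface-EMG recording band
#' (default 20-450 Hz, 4th-order zero-phase Butterworth) and rescaled to the
#' requested RMS.
#'
#' @param n Number of samples.
#' @param sampling_rate_hz Sampling rate.
#' @param rms Target root-mean-square amplitude.
#' @param band Passband edges in Hz.
#' @return Numeric vector of length `n`.
#' @export
band_noise <- function(n, sampling_rate_hz, rms, band = c(20, 450)) {
  if (rms <= 0 || n == 0) return(numeric(n))
  bf <- signal::butter(4, band / (sampling_rate_hz / 2), type = "pass")
  x <- signal::filtfilt(bf, stats::rnorm(n))
  x * (rms / sqrt(mean(x^2)))
}

# trapezoidal force profile: linear rise over rise_s, plateau hold_s, release
force_ramp <- function(t_rel, rise_s, hold_s, target) {
  up <- pmin(pmax(t_rel / rise_s, 0), 1)
  down <- pmin(pmax((rise_s + hold_s + rise_s - t_rel) / rise_s, 0), 1)
  target * pmin(up, down)
}

#' Simulate a complete recording session
#'
#' Renders the scheduled protocol into eight EMG channels plus one force
#' channel: band-limited background noise, saturating stimulus artifacts at
#' every pulse, biphasic evoked responses with the amplitudes drawn by
#' [draw_doublet_amplitudes()], optional volitional-EMG contamination bursts
#' on the agonist channel, and trapezoidal force ramps beginning one reaction
#' time (truncated normal) after each movement cue.
#'
#' Event scheduling is controlled by `protocol$seed`; all remaining draws
#' (amplitudes, reaction times, noise) by `seed`, so a `(protocol,
#' effect_model, seed)` triple is fully reproducible.
#'
#' @param protocol A [protocol_spec()].
#' @param em An [effect_model()].
#' @param seed Integer seed for amplitude/noise/reaction-time draws.
#' @param participant_scale Participant-level amplitude scale factor.
#' @return A [semp_session()] whose `truth` element holds the drawn doublet
#'   amplitudes and `rt_truth` the drawn reaction times (ms) of movement
#'   trials.
#' @export
simulate_session <- function(protocol, em = effect_model(),
                             seed = protocol$seed, participant_scale = 1) {
  events <- schedule_events(protocol)
  withr::with_seed(seed,
    render_session(protocol, em, events, participant_scale))
}

render_session <- function(p, em, events, participant_scale) {
  fs <- p$sampling_rate_hz
  trials <- event_trials(events)
  truth <- draw_doublet_amplitudes(trials, em, p$muscles, participant_scale)

  n <- ceiling((max(events$time_s) + 2) * fs)
  idx_of <- function(t) round(t * fs) + 1L

  template <- evoked_waveform(1, em$response_latency_ms,
                              em$response_duration_ms, fs)
  n_art <- max(1L, round(em$artifact_ms / 1000 * fs))

  stim <- trials[!is.na(trials$pulse1_s), , drop = FALSE]
  pulse_t <- c(stim$pulse1_s, stim$pulse2_s)

  add_at <- function(x, i0, w) {
    ii <- i0 + seq_along(w) - 1L
    keep <- ii >= 1L & ii <= length(x)
    x[ii[keep]] <- x[ii[keep]] + w[keep]
    x
  }

  # movement trials: force onset = cue + reaction time
  mov_tr <- trials[trials$phase %in% c("rt_baseline", "conditioned", "isometric"), , drop = FALSE]
  rt_ms <- draw_rt_ms(nrow(mov_tr), em$rt_mean_ms, em$rt_sd_ms)
  rt_truth <- data.frame(trial_id = mov_tr$trial_id, phase = mov_tr$phase,
                         movement = mov_tr$movement, condition = mov_tr$condition,
                         rt_true_ms = rt_ms)

  signals <- vector("list", length(p$muscles) + 1L)
  names(signals) <- c(p$muscles, "force")

  contam_trials <- unique(truth$trial_id[truth$contaminated])
  for (mus in p$muscles) {
    x <- band_noise(n, fs, em$noise_rms_mv)
    for (t0 in pulse_t) { # saturating stimulus artifact
      i0 <- idx_of(t0)
      ii <- i0:min(i0 + n_art - 1L, n)
      x[ii] <- em$artifact_amp_mv
    }
    tm <- truth[truth$muscle == mus, , drop = FALSE]
    ord <- match(tm$trial_id, stim$trial_id)
    for (k in seq_len(nrow(tm))) {
      x <- add_at(x, idx_of(stim$pulse1_s[ord[k]]), template * tm$r1_true[k])
      x <- add_at(x, idx_of(stim$pulse2_s[ord[k]]), template * tm$r2_true[k])
    }
    # volitional contamination burst on the agonist channel
    for (tid in contam_trials) {
      tr <- trials[trials$trial_id == tid, ]
      if (AGONIST[[tr$movement]] != mus) next
      t_cue <- tr$cue_time_s
      if (is.na(t_cue)) t_cue <- tr$pulse1_s - 0.05
      burst <- band_noise(round(0.6 * fs), fs, em$contamination_rms_mv)
      x <- add_at(x, idx_of(t_cue), burst)
    }
    signals[[mus]] <- x
  }

  force <- stats::rnorm(n, 0, em$force_noise_sd_n)
  for (k in seq_len(nrow(mov_tr))) {
    t_cue <- mov_tr$cue_time_s[k]
    onset <- t_cue + rt_ms[k] / 1000
    hold <- if (mov_tr$phase[k] == "isometric") p$isometric_stim_delay_s + 1 else 0.5
    n_seg <- ceiling((2 * em$force_rise_s + hold) * fs) + 1L
    i0 <- idx_of(onset)
    t_rel <- (seq_len(n_seg) - 1L) / fs
    force <- add_at(force, i0, force_ramp(t_rel, em$force_rise_s, hold, em$force_target_n))
  }
  signals$force <- force

  meta <- list(participant_scale = participant_scale)
  absent <- setdiff(EMG_CHANNELS, p$muscles)
  if (length(absent)) meta$absent_channels <- absent
  semp_session(signals, fs, events, metadata = meta,
               truth = truth, rt_truth = rt_truth)
}

#' Simulate a multi-participant experiment at the amplitude level
#'
#' Draws the ground-truth doublet amplitudes for `n_participants` synthetic
#' participants without rendering signals, producing the table that
#' signal-level simulation followed by [measure_session()] would yield under
#' noiseless extraction (`r1_pp`/`r2_pp` equal the drawn true amplitudes).
#' Each participant receives a lognormal amplitude scale with CV
#' `em$participant_cv`. This is the fast path for Monte-Carlo studies of the
#' statistical pipeline.
#'
#' @param protocol A [protocol_spec()].
#' @param em An [effect_model()].
#' @param n_participants Number of synthetic participants.
#' @param seed Integer seed.
#' @return Doublet table with a `participant` column, suitable for
#'   [analyze_modulation()] and [build_probability_map()].
#' @export
simulate_experiment <- function(protocol, em = effect_model(),
                                n_participants = 13, seed = 1L) {
  trials <- event_trials(schedule_events(protocol))
  withr::with_seed(seed, {
    out <- vector("list", n_participants)
    for (pp in seq_len(n_participants)) {
      scale_p <- rlnorm_mean(1, 1, em$participant_cv)
      tr <- draw_doublet_amplitudes(trials, em, protocol$muscles, scale_p)
      tr$participant <- pp
      out[[pp]] <- tr
    }
    res <- do.call(rbind, out)
    names(res)[names(res) == "r1_true"] <- "r1_pp"
    names(res)[names(res) == "r2_true"] <- "r2_pp"
    rownames(res) <- NULL
    res
  })
}

#' Simulate a block of reaction-time trials (force channel only)
#'
#' Generates `n` independent force traces, each with a cue at `cue_time_s`
#' and a trapezoidal contraction starting one reaction time later. Reaction
#' times are drawn from a normal distribution truncated at zero.
#'
#' @param n Number of trials.
#' @param rt_mean_ms,rt_sd_ms Reaction-time distribution (ms).
#' @param em An [effect_model()] supplying force-ramp and noise settings.
#' @param cue_time_s Cue time within each trace (s).
#' @param trial_dur_s Trace duration (s).
#' @param sampling_rate_hz Sampling rate.
#' @param seed Integer seed.
#' @return List with `traces` (list of numeric vectors), `true_rt_ms`,
#'   `cue_time_s` and `sampling_rate_hz`.
#' @export
simulate_rt_block <- function(n, rt_mean_ms = 210.2, rt_sd_ms = 47.7,
                              em = effect_model(), cue_time_s = 1,
                              trial_dur_s = 2.5, sampling_rate_hz = 2000,
                              seed = 1L) {
  withr::with_seed(seed, {
    rt <- draw_rt_ms(n, rt_mean_ms, rt_sd_ms)
    n_samp <- round(trial_dur_s * sampling_rate_hz)
    t <- (seq_len(n_samp) - 1L) / sampling_rate_hz
    traces <- lapply(seq_len(n), function(k) {
      onset <- cue_time_s + rt[k] / 1000
      stats::rnorm(n_samp, 0, em$force_noise_sd_n) +
        force_ramp(t - onset, em$force_rise_s, 0.5, em$force_target_n)
    })
    list(traces = traces, true_rt_ms = rt, cue_time_s = cue_time_s,
         sampling_rate_hz = sampling_rate_hz)
  })
}

#' Sigmoidal recruitment mean amplitude
#'
#' Expected R1 peak-to-peak amplitude as a function of stimulation intensity:
#' a logistic recruitment curve on top of a sub-threshold noise floor.
#'
#' @param intensity_ma Stimulation intensities (mA).
#' @param midpoint_ma Intensity of half-maximal recruitment (mA).
#' @param slope_ma Logistic slope parameter (mA).
#' @param max_amp_mv Plateau amplitude (mV).
#' @param floor_mv Sub-threshold measurement floor (mV).
#' @return Mean amplitudes (mV).
#' @export
recruitment_mean <- function(intensity_ma, midpoint_ma = 50, slope_ma = 4,
                             max_amp_mv = 1.5, floor_mv = 0.005) {
  floor_mv + max_amp_mv * stats::plogis((intensity_ma - midpoint_ma) / slope_ma)
}

#' Simulate a recruitment-curve block
#'
#' Stimulation intensity is stepped up (5 mA steps by default) with a few
#' pulses per intensity; per-pulse amplitudes are lognormal around the
#' logistic recruitment mean.
#'
#' @param intensities_ma Increasing stimulation intensities (mA).
#' @param n_pulses Pulses delivered at each intensity.
#' @param cv Trial-to-trial lognormal CV.
#' @param seed Integer seed.
#' @inheritParams recruitment_mean
#' @return Data frame with `intensity_mA`, `pulse`, `r1_pp`.
#' @export
simulate_recruitment <- function(intensities_ma = seq(30, 70, by = 5),
                                 n_pulses = 3, midpoint_ma = 50, slope_ma = 4,
                                 max_amp_mv = 1.5, floor_mv = 0.005,
                                 cv = 0.1, seed = 1L) {
  withr::with_seed(seed, {
    grid <- expand.grid(pulse = seq_len(n_pulses), intensity_mA = intensities_ma,
                        KEEP.OUT.ATTRS = FALSE)
    mu <- recruitment_mean(grid$intensity_mA, midpoint_ma, slope_ma,
                           max_amp_mv, floor_mv)
    data.frame(intensity_mA = grid$intensity_mA, pulse = grid$pulse,
               r1_pp = rlnorm_mean(nrow(grid), mu, cv))
  })
}
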