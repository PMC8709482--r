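#' Channel and factor-level constants
#'
#' Eight bilateral leg-muscle EMG channels (vastus lateralis, medial
#' hamstrings, tibialis anterior, soleus; left/right) plus one force channel,
#' the four instructed movements, and the conditioning modalities.
#'
#' @format Character vectors.
#' @name semp_constants
NULL

#' @rdname semp_constants
#' @export
EMG_CHANNELS <- c("LVL", "LMH", "LTA", "LSOL", "RVL", "RMH", "RTA", "RSOL")

#' @rdname semp_constants
#' @export
SESSION_CHANNELS <- c(EMG_CHANNELS, "force")

#' @rdname semp_constants
#' @export
MOVEMENTS <- c("knee_extension", "knee_flexion", "dorsiflexion", "plantarflexion")

#' @rdname semp_constants
#' @export
CONDITIONS <- c("auditory", "tactile", "isometric")

#' Agonist muscle (left leg) for each instructed movement.
#' @keywords internal
AGONIST <- c(
  knee_extension = "LVL",
  knee_flexion   = "LMH",
  dorsiflexion   = "LTA",
  plantarflexion = "LSOL"
)

EVENT_KINDS <- c("cue_auditory", "cue_tactile", "stim_pulse", "contraction_cue")
TRIAL_PHASES <- c("rt_baseline", "control_pre", "conditioned", "control_post", "isometric")

#' Construct a stimulation/conditioning protocol
#'
#' Describes one experimental session: which movements and conditioning
#' modalities are tested, the condition-test intervals (CTIs) between cue and
#' test doublet, repetition counts, inter-cue spacing, and sampling rate.
#' Stimulation is always a doublet: two pulses separated by `isi_ms`.
#'
#' @param movements Character vector, subset of [MOVEMENTS].
#' @param conditions Character vector, subset of [CONDITIONS].
#' @param cti_list_ms Strictly increasing numeric vector of condition-test
#'   intervals in ms (cue to first pulse).
#' @param reps_per_cti Conditioned trials per CTI per movement x condition.
#' @param controls_pre,controls_post Resting control doublets recorded before
#'   and after each movement block.
#' @param rt_reps Fast-contraction trials (no stimulation) used to measure the
#'   baseline reaction time, once per movement.
#' @param isometric_reps Doublets delivered during maintained contraction when
#'   `"isometric"` is among `conditions`.
#' @param cue_spacing_s Length-2 numeric `(min, max)`: pseudorandom spacing
#'   between successive cues, seconds.
#' @param control_spacing_s Fixed spacing between control doublets, seconds.
#' @param isometric_stim_delay_s Delay of the doublet after contraction onset
#'   in isometric trials, seconds.
#' @param isi_ms Inter-stimulus interval of the doublet, ms.
#' @param sampling_rate_hz Sampling rate of all channels, samples/s.
#' @param muscles EMG channels to simulate/analyse (default all eight).
#' @param seed Integer seed governing the randomized CTI order and cue spacing.
#'
#' @return An object of class `semp_protocol` (a validated list).
#' @seealso [default_protocol()] for the standard session layout.
#' @export
protocol_spec <- function(movements = MOVEMENTS,
                          conditions = c("auditory", "tactile", "isometric"),
                          cti_list_ms = c(50, 100, 150, 200, 250),
                          reps_per_cti = 10,
                          controls_pre = 10,
                          controls_post = 10,
                          rt_reps = 10,
                          isometric_reps = 10,
                          cue_spacing_s = c(5, 7),
                          control_spacing_s = 5,
                          isometric_stim_delay_s = 2,
                          isi_ms = 50,
                          sampling_rate_hz = 2000,
                          muscles = EMG_CHANNELS,
                          seed = 1L) {
  p <- structure(
    list(
      movements = match.arg(movements, MOVEMENTS, several.ok = TRUE),
      conditions = match.arg(conditions, CONDITIONS, several.ok = TRUE),
      cti_list_ms = as.numeric(cti_list_ms),
      reps_per_cti = as.integer(reps_per_cti),
      controls_pre = as.integer(controls_pre),
      controls_post = as.integer(controls_post),
      rt_reps = as.integer(rt_reps),
      isometric_reps = as.integer(isometric_reps),
      cue_spacing_s = as.numeric(cue_spacing_s),
      control_spacing_s = as.numeric(control_spacing_s),
      isometric_stim_delay_s = as.numeric(isometric_stim_delay_s),
      isi_ms = as.numeric(isi_ms),
      sampling_rate_hz = as.numeric(sampling_rate_hz),
      muscles = match.arg(muscles, EMG_CHANNELS, several.ok = TRUE),
      seed = as.integer(seed)
    ),
    class = "semp_protocol"
  )
  validate_protocol(p)
  p
}

validate_protocol <- function(p) {
  stopifnot(inherits(p, "semp_protocol"))
  if (length(p$cti_list_ms) == 0 || any(diff(p$cti_list_ms) <= 0)) {
    stop("cti_list_ms must be non-empty and strictly increasing", call. = FALSE)
  }
  counts <- c(p$reps_per_cti, p$controls_pre, p$controls_post)
  if (any(counts <= 0)) stop("repetition counts must be > 0", call. = FALSE)
  if (length(p$cue_spacing_s) != 2 || p$cue_spacing_s[1] > p$cue_spacing_s[2]) {
    stop("cue_spacing_s must be (min, max) with min <= max", call. = FALSE)
  }
  if (p$sampling_rate_hz <= 0) stop("sampling_rate_hz must be > 0", call. = FALSE)
  # a trial must be over (response window included) before the next cue
  min_needed <- max(p$cti_list_ms) / 1000 + p$isi_ms / 1000 + 0.1
  if (p$cue_spacing_s[1] < min_needed) {
    stop(sprintf(
      "cue spacing %.3f s too small for CTI %.0f ms + doublet response window",
      p$cue_spacing_s[1], max(p$cti_list_ms)
    ), call. = FALSE)
  }
  invisible(p)
}

#' Standard session protocol
#'
#' The default conditioning layout: CTIs of 50, 100, 150, 200 and 250 ms, ten
#' conditioned doublets per CTI, ten resting control doublets before and ten
#' after each movement block (twenty controls per baseline), doublet
#' inter-stimulus interval 50 ms, cues every 5-7 s with pseudorandom spacing,
#' isometric doublets 2 s after contraction onset, all channels sampled at
#' 2000 Hz.
#'
#' @param ... Overrides passed on to [protocol_spec()].
#' @return A `semp_protocol`.
#' @examples
#' p <- default_protocol()
#' p$cti_list_ms
#' @export
default_protocol <- function(...) {
  protocol_spec(...)
}

#' @export
print.semp_protocol <- function(x, ...) {
  cat("<semp_protocol>\n")
  cat("  movements:  ", paste(x$movements, collapse = ", "), "\n")
  cat("  conditions: ", paste(x$conditions, collapse = ", "), "\n")
  cat("  CTIs (ms):  ", paste(x$cti_list_ms, collapse = ", "),
      " x", x$reps_per_cti, "reps\n")
  cat("  controls:   ", x$controls_pre, "pre +", x$controls_post, "post\n")
  cat("  sampling:   ", x$sampling_rate_hz, "Hz, ISI", x$isi_ms, "ms, seed",
      x$seed, "\n")
  invisible(x)
}

#' Construct a generative effect model
#'
#' Encodes the ground truth a synthetic session is drawn from: per-cell
#' multiplicative modulation of the first-response (R1) amplitude relative to
#' rest, the expected second-to-first response ratio (post-activation
#' depression level), trial-to-trial amplitude variability, reaction-time
#' distribution, background noise, and contamination by volitional EMG.
#'
#' `modulation` and `depression` are either a single number applied everywhere
#' or a lookup data frame with columns `muscle`, `movement`, `condition`,
#' `cti_ms`, `value`; `NA` in a key column acts as a wildcard, and the most
#' specific matching row wins. Control (resting) doublets always have
#' modulation 1; their depression level is looked up with
#' `condition = "control"`, which normally falls through to the wildcard
#' resting value.
#'
#' @param modulation R1 modulation factor(s) (> 0, 1 = no modulation).
#' @param depression Expected R2/R1 ratio(s), in `[0, 1.5]`.
#' @param amplitude_cv Coefficient of variation of the lognormal
#'   trial-to-trial amplitude noise.
#' @param base_amplitude_mv Resting mean R1 peak-to-peak amplitude (mV); a
#'   single value or a named vector per muscle.
#' @param participant_cv Between-participant lognormal CV of the base
#'   amplitude scale.
#' @param rt_mean_ms,rt_sd_ms Reaction-time distribution (normal, truncated at
#'   0 by redrawing), ms.
#' @param noise_rms_mv RMS of the 20-450 Hz band-limited background EMG noise
#'   (mV).
#' @param contamination_prob Probability that a conditioned trial carries a
#'   volitional-EMG burst overlapping the response window.
#' @param contamination_rms_mv RMS of the contamination burst (mV).
#' @param artifact_amp_mv Amplitude of the saturating stimulus artifact (mV).
#' @param artifact_ms Duration of the stimulus artifact (ms).
#' @param response_latency_ms,response_duration_ms Evoked-response template
#'   placement after each pulse (ms).
#' @param force_target_n Plateau force of a fast contraction (N), nominally
#'   5-10% of maximum voluntary contraction.
#' @param force_rise_s Linear rise time of the force ramp (s).
#' @param force_noise_sd_n Gaussian noise SD on the force channel (N).
#'
#' @return An object of class `semp_effect_model`.
#' @export
effect_model <- function(modulation = 1,
                         depression = 0.2,
                         amplitude_cv = 0.2,
                         base_amplitude_mv = 0.5,
                         participant_cv = 0.3,
                         rt_mean_ms = 210.2,
                         rt_sd_ms = 47.7,
                         noise_rms_mv = 0.01,
                         contamination_prob = 0,
                         contamination_rms_mv = 0.05,
                         artifact_amp_mv = 5,
                         artifact_ms = 2,
                         response_latency_ms = 15,
                         response_duration_ms = 25,
                         force_target_n = 20,
                         force_rise_s = 0.15,
                         force_noise_sd_n = 0.02) {
  em <- structure(
    list(
      modulation = modulation,
      depression = depression,
      amplitude_cv = amplitude_cv,
      base_amplitude_mv = base_amplitude_mv,
      participant_cv = participant_cv,
      rt_mean_ms = rt_mean_ms,
      rt_sd_ms = rt_sd_ms,
      noise_rms_mv = noise_rms_mv,
      contamination_prob = contamination_prob,
      contamination_rms_mv = contamination_rms_mv,
      artifact_amp_mv = artifact_amp_mv,
      artifact_ms = artifact_ms,
      response_latency_ms = response_latency_ms,
      response_duration_ms = response_duration_ms,
      force_target_n = force_target_n,
      force_rise_s = force_rise_s,
      force_noise_sd_n = force_noise_sd_n
    ),
    class = "semp_effect_model"
  )
  validate_effect_model(em)
  em
}

validate_effect_model <- function(em) {
  check_map <- function(map, name, lo, hi) {
    vals <- if (is.data.frame(map)) map$value else map
    if (!is.numeric(vals) || any(!is.finite(vals)) ||
        any(vals < lo) || any(vals > hi)) {
      stop(sprintf("%s values must be finite and in [%g, %g]", name, lo, hi),
           call. = FALSE)
    }
    if (is.data.frame(map) &&
        !all(c("muscle", "movement", "condition", "cti_ms", "value") %in% names(map))) {
      stop(sprintf(
        "%s lookup table needs columns muscle, movement, condition, cti_ms, value",
        name
      ), call. = FALSE)
    }
  }
  check_map(em$modulation, "modulation", .Machine$double.eps, Inf)
  check_map(em$depression, "depression", 0, 1.5)
  stopifnot(
    em$amplitude_cv >= 0, em$rt_sd_ms >= 0, em$noise_rms_mv >= 0,
    em$contamination_prob >= 0, em$contamination_prob <= 1,
    all(em$base_amplitude_mv > 0)
  )
  invisible(em)
}

#' Build a modulation/depression lookup table
#'
#' Convenience constructor for the `modulation`/`depression` arguments of
#' [effect_model()]. Rows with `NA` act as wildcards for that key.
#'
#' @param ... Data-frame columns (`muscle`, `movement`, `condition`, `cti_ms`,
#'   `value`); omitted keys become all-`NA` wildcards.
#' @return A lookup data frame.
#' @examples
#' effect_table(muscle = "LVL", cti_ms = c(200, 250), value = c(2, 4))
#' @export
effect_table <- function(...) {
  args <- list(...)
  if (is.null(args$value)) stop("effect_table() needs a `value` column", call. = FALSE)
  n <- max(lengths(args))
  full <- list(
    muscle = args$muscle %||% NA_character_,
    movement = args$movement %||% NA_character_,
    condition = args$condition %||% NA_character_,
    cti_ms = args$cti_ms %||% NA_real_,
    value = args$value
  )
  as.data.frame(lapply(full, rep_len, n))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Resolve an effect map at one analysis cell
#'
#' @param map Scalar or lookup data frame (see [effect_model()]).
#' @param muscle,movement,condition Cell keys.
#' @param cti_ms Condition-test interval, or `NA` for rest/isometric.
#' @param default Value when no row matches.
#' @return A single numeric value (most specific matching row wins).
#' @keywords internal
lookup_effect <- function(map, muscle, movement, condition, cti_ms, default = 1) {
  if (!is.data.frame(map)) return(as.numeric(map))
  key_match <- function(col, x) is.na(col) | (!is.na(x) & col == x)
  ok <- key_match(map$muscle, muscle) &
    key_match(map$movement, movement) &
    key_match(map$condition, condition) &
    key_match(map$cti_ms, cti_ms)
  if (!any(ok)) return(default)
  hit <- map[ok, , drop = FALSE]
  spec <- rowSums(!is.na(hit[, c("muscle", "movement", "condition", "cti_ms")]))
  hit$value[which.max(spec)]
}
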