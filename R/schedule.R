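#' Schedule cues and stimulation doublets for a session
#'
#' Lays out all trials of a protocol on a common time axis. Each movement is
#' preceded by a reaction-time block (fast contractions on the auditory cue,
#' no stimulation). Every movement x condition block then consists of resting
#' control doublets (pre), conditioned trials with a cue followed by the test
#' doublet at a randomized condition-test interval, and resting control
#' doublets (post). Isometric blocks place the doublet a fixed delay after
#' contraction onset. The CTI order is shuffled within each block and cue
#' spacing drawn uniformly from the protocol's `(min, max)` range, both under
#' the protocol seed, so the same protocol always yields the same table.
#'
#' @param protocol A [protocol_spec()].
#' @return An event table (data frame) with one row per event:
#'   `time_s`, `kind` (`cue_auditory`, `cue_tactile`, `contraction_cue`,
#'   `stim_pulse`), `trial_id`, `movement`, `condition`, `phase`
#'   (`rt_baseline`, `control_pre`, `conditioned`, `control_post`,
#'   `isometric`), `cti_ms` (`NA` outside conditioned trials) and
#'   `pulse_index` (1/2 for stimulation pulses, `NA` otherwise). Times are
#'   strictly increasing.
#' @export
schedule_events <- function(protocol) {
  validate_protocol(protocol)
  withr::with_seed(protocol$seed, schedule_events_impl(protocol))
}

schedule_events_impl <- function(p) {
  isi_s <- p$isi_ms / 1000
  rows <- vector("list", 0L)
  t <- 5 # settle time before the first trial
  trial <- 0L

  push <- function(time_s, kind, trial_id, movement, condition, phase,
                   cti_ms = NA_real_, pulse_index = NA_integer_) {
    rows[[length(rows) + 1L]] <<- data.frame(
      time_s = time_s, kind = kind, trial_id = trial_id,
      movement = movement, condition = condition, phase = phase,
      cti_ms = cti_ms, pulse_index = pulse_index
    )
  }

  cue_kind <- c(auditory = "cue_auditory", tactile = "cue_tactile")
  draw_spacing <- function() stats::runif(1, p$cue_spacing_s[1], p$cue_spacing_s[2])

  for (mov in p$movements) {
    # reaction-time baseline: fast contractions on the auditory cue, no TSS
    for (i in seq_len(p$rt_reps)) {
      trial <- trial + 1L
      push(t, "cue_auditory", trial, mov, "auditory", "rt_baseline")
      t <- t + draw_spacing()
    }
    for (cond in p$conditions) {
      add_controls <- function(n, phase) {
        for (i in seq_len(n)) {
          trial <<- trial + 1L
          push(t, "stim_pulse", trial, mov, cond, phase, pulse_index = 1L)
          push(t + isi_s, "stim_pulse", trial, mov, cond, phase, pulse_index = 2L)
          t <<- t + p$control_spacing_s
        }
      }
      add_controls(p$controls_pre, "control_pre")
      if (cond == "isometric") {
        for (i in seq_len(p$isometric_reps)) {
          trial <- trial + 1L
          t0 <- t + p$isometric_stim_delay_s
          push(t, "contraction_cue", trial, mov, cond, "isometric")
          push(t0, "stim_pulse", trial, mov, cond, "isometric", pulse_index = 1L)
          push(t0 + isi_s, "stim_pulse", trial, mov, cond, "isometric", pulse_index = 2L)
          t <- t + p$isometric_stim_delay_s + 2 + draw_spacing()
        }
      } else {
        ctis <- sample(rep(p$cti_list_ms, p$reps_per_cti))
        for (cti in ctis) {
          trial <- trial + 1L
          t0 <- t + cti / 1000
          push(t, cue_kind[[cond]], trial, mov, cond, "conditioned", cti_ms = cti)
          push(t0, "stim_pulse", trial, mov, cond, "conditioned",
               cti_ms = cti, pulse_index = 1L)
          push(t0 + isi_s, "stim_pulse", trial, mov, cond, "conditioned",
               cti_ms = cti, pulse_index = 2L)
          t <- t + draw_spacing()
        }
      }
      add_controls(p$controls_post, "control_post")
    }
  }

  ev <- do.call(rbind, rows)
  ev <- ev[order(ev$time_s), , drop = FALSE]
  rownames(ev) <- NULL
  if (any(diff(ev$time_s) <= 0)) {
    stop("scheduling error: overlapping events (cue spacing too small)", call. = FALSE)
  }
  ev
}

#' Trials of an event table, one row per trial
#' @param events An event table from [schedule_events()].
#' @return Data frame with `trial_id`, `movement`, `condition`, `phase`,
#'   `cti_ms`, `cue_time_s` (`NA` for control doublets), `pulse1_s`,
#'   `pulse2_s` (`NA` for unstimulated trials).
#' @export
event_trials <- function(events) {
  ids <- unique(events$trial_id)
  first <- events[match(ids, events$trial_id), c("trial_id", "movement", "condition", "phase", "cti_ms")]
  cue <- events[events$kind %in% c("cue_auditory", "cue_tactile", "contraction_cue"), ]
  p1 <- events[events$kind == "stim_pulse" & events$pulse_index == 1L, ]
  p2 <- events[events$kind == "stim_pulse" & events$pulse_index == 2L, ]
  first$cue_time_s <- cue$time_s[match(ids, cue$trial_id)]
  first$pulse1_s <- p1$time_s[match(ids, p1$trial_id)]
  first$pulse2_s <- p2$time_s[match(ids, p2$trial_id)]
  rownames(first) <- NULL
  first
}
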