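# Session container and on-disk format: one directory per session holding a
# JSON manifest, a wide CSV of signals (one column per channel), the event
# table, and (for synthetic sessions) the generator ground truth.

#' Construct a recording session
#'
#' Bundles the multi-channel signals, sampling rate, event table and free-form
#' metadata of one recording. EMG channels are in mV, force in N.
#'
#' @param signals Named list of equal-length numeric vectors; names are
#'   channel names (see [SESSION_CHANNELS]).
#' @param sampling_rate_hz Sampling rate (> 0).
#' @param events Event table (see [schedule_events()]).
#' @param metadata Free-form named list (participant id, notes, ...).
#' @param truth,rt_truth Optional generator ground-truth tables (synthetic
#'   sessions only).
#' @return An object of class `semp_session`.
#' @export
semp_session <- function(signals, sampling_rate_hz, events,
                         metadata = list(), truth = NULL, rt_truth = NULL) {
  s <- structure(
    list(signals = signals, sampling_rate_hz = sampling_rate_hz,
         events = events, metadata = metadata,
         truth = truth, rt_truth = rt_truth),
    class = "semp_session"
  )
  v <- validate_session(s)
  fatal <- v$code %in% c("CHANNEL_DUPLICATE", "LENGTH_MISMATCH", "BAD_SAMPLING_RATE")
  if (any(fatal)) stop(paste(v$message[fatal], collapse = "; "), call. = FALSE)
  s
}

#' @export
print.semp_session <- function(x, ...) {
  n <- length(x$signals[[1]])
  cat("<semp_session>", length(x$signals), "channels x", n, "samples @",
      x$sampling_rate_hz, "Hz (", round(n / x$sampling_rate_hz, 1), "s ),",
      nrow(x$events), "events\n")
  invisible(x)
}

#' Validate a session against its structural invariants
#'
#' Checks channel presence and uniqueness, equal signal lengths, sampling
#' rate, event kinds, monotone and in-range event times, per-trial pulse
#' bookkeeping, and the doublet inter-stimulus interval (tolerance: one
#' sample). Violations are returned, never thrown.
#'
#' @param session A `semp_session` (or a structurally similar list).
#' @param expected_isi_ms Expected doublet inter-stimulus interval (ms).
#' @param required_channels Channels that must be present unless declared
#'   absent in `metadata$absent_channels`.
#' @return Data frame with columns `code`, `message`, `trial_id`
#'   (zero rows when all invariants hold). Codes include
#'   `CHANNEL_MISSING`, `CHANNEL_DUPLICATE`, `LENGTH_MISMATCH`,
#'   `BAD_SAMPLING_RATE`, `UNKNOWN_EVENT_KIND`, `NONMONOTONE_TIME`,
#'   `EVENT_OUT_OF_RANGE`, `PULSE_COUNT`, `ISI_MISMATCH`.
#' @export
validate_session <- function(session, expected_isi_ms = 50,
                             required_channels = SESSION_CHANNELS) {
  out <- list()
  bad <- function(code, message, trial_id = NA_integer_) {
    out[[length(out) + 1L]] <<- data.frame(code = code, message = message,
                                           trial_id = trial_id)
  }

  sig <- session$signals
  nm <- names(sig)
  if (anyDuplicated(nm)) bad("CHANNEL_DUPLICATE", "duplicate channel names")
  absent <- session$metadata$absent_channels
  miss <- setdiff(required_channels, c(nm, absent))
  for (m in miss) bad("CHANNEL_MISSING", paste("required channel missing:", m))
  lens <- lengths(sig)
  if (length(unique(lens)) > 1) {
    bad("LENGTH_MISMATCH", paste("signal lengths differ:",
                                 paste(unique(lens), collapse = ", ")))
  }
  fs <- session$sampling_rate_hz
  if (!is.numeric(fs) || length(fs) != 1 || !is.finite(fs) || fs <= 0) {
    bad("BAD_SAMPLING_RATE", "sampling_rate_hz must be a positive number")
    fs <- NA_real_
  }

  ev <- session$events
  if (!is.null(ev) && nrow(ev) > 0) {
    unknown <- setdiff(unique(ev$kind), EVENT_KINDS)
    for (k in unknown) bad("UNKNOWN_EVENT_KIND", paste("unknown event kind:", k))
    if (is.unsorted(ev$time_s)) bad("NONMONOTONE_TIME", "event times not non-decreasing")
    if (!is.na(fs) && length(lens) > 0) {
      dur <- max(lens) / fs
      oob <- which(ev$time_s < 0 | ev$time_s > dur)
      for (i in oob) {
        bad("EVENT_OUT_OF_RANGE",
            sprintf("event at %.3f s outside recording of %.3f s", ev$time_s[i], dur),
            ev$trial_id[i])
      }
    }
    pulses <- ev[ev$kind == "stim_pulse", , drop = FALSE]
    for (tid in unique(pulses$trial_id)) {
      tp <- pulses[pulses$trial_id == tid, , drop = FALSE]
      if (nrow(tp) != 2) {
        bad("PULSE_COUNT",
            sprintf("trial %s has %d stim_pulse rows (expected 2)", tid, nrow(tp)), tid)
        next
      }
      isi_ms <- 1000 * abs(diff(sort(tp$time_s)))
      tol_ms <- if (is.na(fs)) 0.5 else 1000 / fs
      if (abs(isi_ms - expected_isi_ms) > tol_ms + 1e-9) {
        bad("ISI_MISMATCH",
            sprintf("trial %s inter-stimulus interval %.2f ms (expected %.0f)",
                    tid, isi_ms, expected_isi_ms), tid)
      }
    }
  }

  if (length(out) == 0) {
    data.frame(code = character(), message = character(), trial_id = integer())
  } else {
    do.call(rbind, out)
  }
}

#' Write a session to a directory
#'
#' Writes `manifest.json` (channels, units, sampling rate, file names,
#' metadata), `signals.csv` (wide, one column per channel), `events.csv`, and
#' `truth.csv`/`rt_truth.csv` when generator ground truth is attached.
#' Doubles are serialized with shortest round-trip precision, so
#' [read_session()] recovers the session losslessly.
#'
#' @param session A [semp_session()].
#' @param path Directory to create/fill.
#' @return The manifest path, invisibly.
#' @export
write_session <- function(session, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  nm <- names(session$signals)
  manifest <- list(
    format = "semp-session",
    version = 1L,
    sampling_rate_hz = session$sampling_rate_hz,
    n_samples = length(session$signals[[1]]),
    channels = data.frame(name = nm,
                          unit = ifelse(nm == "force", "N", "mV")),
    signals_file = "signals.csv",
    events_file = "events.csv",
    metadata = session$metadata
  )
  write_exact_csv(as.data.frame(session$signals, check.names = FALSE),
                  file.path(path, "signals.csv"))
  write_exact_csv(session$events, file.path(path, "events.csv"))
  if (!is.null(session$truth)) {
    manifest$truth_file <- "truth.csv"
    write_exact_csv(session$truth, file.path(path, "truth.csv"))
  }
  if (!is.null(session$rt_truth)) {
    manifest$rt_truth_file <- "rt_truth.csv"
    write_exact_csv(session$rt_truth, file.path(path, "rt_truth.csv"))
  }
  mp <- file.path(path, "manifest.json")
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(mp)
}

# CSV writer that round-trips doubles exactly: 17 significant digits are
# always sufficient to recover the original IEEE double on read.
write_exact_csv <- function(df, file) {
  for (j in seq_along(df)) {
    if (is.double(df[[j]])) {
      v <- sprintf("%.17g", df[[j]])
      v[is.na(df[[j]])] <- NA_character_
      df[[j]] <- v
    }
  }
  readr::write_csv(df, file, progress = FALSE, na = "")
}

# fread parses doubles with correctly rounded (exact) conversion, which the
# lossless round-trip guarantee relies on
read_session_csv <- function(file, spec) {
  as.data.frame(data.table::fread(file, colClasses = spec,
                                  na.strings = c("", "NA"), data.table = FALSE,
                                  showProgress = FALSE))
}

#' Read a session from a directory
#'
#' Inverse of [write_session()]. The loaded session is validated; structural
#' violations raise an error naming the offending record.
#'
#' @param path Session directory containing `manifest.json`.
#' @param check When `TRUE` (default), fail on validation violations.
#' @return A [semp_session()].
#' @export
read_session <- function(path, check = TRUE) {
  mp <- file.path(path, "manifest.json")
  if (!file.exists(mp)) stop("no manifest.json in ", path, call. = FALSE)
  manifest <- jsonlite::read_json(mp, simplifyVector = TRUE)
  for (f in c(manifest$signals_file, manifest$events_file)) {
    if (!file.exists(file.path(path, f))) {
      stop("session file missing: ", f, call. = FALSE)
    }
  }
  sig_df <- read_session_csv(file.path(path, manifest$signals_file), "double")
  events <- read_session_csv(
    file.path(path, manifest$events_file),
    c(time_s = "double", kind = "character", trial_id = "integer",
      movement = "character", condition = "character", phase = "character",
      cti_ms = "double", pulse_index = "integer")
  )
  truth <- NULL
  if (!is.null(manifest$truth_file)) {
    truth <- read_session_csv(
      file.path(path, manifest$truth_file),
      c(trial_id = "integer", movement = "character", condition = "character",
        phase = "character", cti_ms = "double", muscle = "character",
        r1_true = "double", r2_true = "double", contaminated = "logical")
    )
  }
  rt_truth <- NULL
  if (!is.null(manifest$rt_truth_file)) {
    rt_truth <- read_session_csv(
      file.path(path, manifest$rt_truth_file),
      c(trial_id = "integer", phase = "character", movement = "character",
        condition = "character", rt_true_ms = "double")
    )
  }
  meta <- manifest$metadata
  if (is.null(meta)) meta <- list()
  s <- structure(
    list(signals = as.list(sig_df),
         sampling_rate_hz = manifest$sampling_rate_hz,
         events = events, metadata = meta,
         truth = truth, rt_truth = rt_truth),
    class = "semp_session"
  )
  if (check) {
    v <- validate_session(s)
    if (nrow(v) > 0) {
      stop("session validation failed:\n",
           paste(sprintf("  [%s] %s", v$code, v$message), collapse = "\n"),
           call. = FALSE)
    }
  }
  s
}
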