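#' Biphasic evoked-response template
#'
#' A damped biphasic template (one positive then one negative lobe) standing
#' in for a compound muscle response: zero before `latency_ms`, one cycle of a
#' exponentially damped sine over `duration_ms`, zero afterwards. The sampled
#' waveform is rescaled so its realized peak-to-peak amplitude equals
#' `amplitude_pp` exactly.
#'
#' @param amplitude_pp Peak-to-peak amplitude (mV), >= 0.
#' @param latency_ms Onset latency after the stimulation pulse (ms).
#' @param duration_ms Duration of the biphasic deflection (ms).
#' @param sampling_rate_hz Sampling rate (samples/s). Must resolve each lobe
#'   with at least 4 samples.
#' @return Numeric vector covering `[0, latency_ms + duration_ms)` at the
#'   requested sampling rate.
#' @examples
#' w <- evoked_waveform(1, 15, 25, 2000)
#' max(w) - min(w) # exactly 1
#' @export
evoked_waveform <- function(amplitude_pp, latency_ms = 15, duration_ms = 25,
                            sampling_rate_hz = 2000) {
  stopifnot(amplitude_pp >= 0, duration_ms > 0, latency_ms >= 0)
  dur_s <- duration_ms / 1000
  if (sampling_rate_hz * dur_s / 2 < 4) {
    stop("sampling rate too low to resolve the evoked waveform (< 4 samples per lobe)",
         call. = FALSE)
  }
  n_total <- round((latency_ms + duration_ms) / 1000 * sampling_rate_hz)
  n_lat <- round(latency_ms / 1000 * sampling_rate_hz)
  n_wave <- n_total - n_lat
  u <- seq_len(n_wave) / n_wave            # (0, 1]
  shape <- sin(2 * pi * u) * exp(-1.5 * u) # positive lobe, damped negative lobe
  pp <- max(shape) - min(shape)
  w <- numeric(n_total)
  if (amplitude_pp > 0) w[n_lat + seq_len(n_wave)] <- shape * (amplitude_pp / pp)
  w
}
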