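# Shared fixtures: small protocols and effect models built in code.

tiny_protocol <- function(..., seed = 7) {
  default_protocol(
    movements = "plantarflexion", conditions = "auditory",
    reps_per_cti = 3, controls_pre = 3, controls_post = 3, rt_reps = 2,
    muscles = c("LSOL", "LTA"), seed = seed, ...
  )
}

# one-muscle protocol for Monte-Carlo work on the statistics
mc_protocol <- function(..., seed = 1) {
  default_protocol(
    movements = "plantarflexion", conditions = "auditory",
    rt_reps = 1, muscles = "LSOL", seed = seed, ...
  )
}

quiet_model <- function(...) {
  effect_model(noise_rms_mv = 0, force_noise_sd_n = 0, ...)
}

# a small complete session rendered once per test file
make_tiny_session <- function(em = effect_model(noise_rms_mv = 0.005), seed = 11) {
  simulate_session(tiny_protocol(), em, seed = seed)
}

# random fuzzed session for round-trip tests
fuzz_session <- function(n = 400, fs = 2000) {
  sig <- stats::setNames(
    lapply(SESSION_CHANNELS, function(ch) stats::rnorm(n)),
    SESSION_CHANNELS
  )
  t1 <- stats::runif(1, 0.02, n / fs / 3)
  events <- data.frame(
    time_s = c(t1, t1 + 0.05),
    kind = "stim_pulse", trial_id = 1L,
    movement = sample(MOVEMENTS, 1), condition = "auditory",
    phase = "control_pre", cti_ms = NA_real_, pulse_index = 1:2
  )
  semp_session(sig, fs, events, metadata = list(note = "fuzz"))
}
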