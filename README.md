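# semp — simulation and analysis of spinally evoked motor potentials

Transcutaneous spinal stimulation (TSS) over the lumbosacral enlargement
elicits reflex motor responses — spinally evoked motor potentials — in
multiple leg muscles at once. Delivered as a doublet (two pulses 50 ms
apart), the stimulus probes two things simultaneously: the excitability of
the motor pools (the first response, **R1**) and post-activation depression
at the activated synapses (the second response, **R2**, normally suppressed
at rest and quantified as the **R2/R1 ratio**). Applying the test doublet at
a short **condition-test interval (CTI)** after a movement cue — before any
EMG or force change — exposes how descending drive re-tunes spinal circuitry
during movement *preparation*.

`semp` is an R package for researchers running or re-analysing this kind of
conditioning experiment. It provides:

- a **synthetic-session generator**: multi-channel surface EMG (2000 Hz,
  eight bilateral leg muscles: VL, MH, TA, SOL) plus a force channel, with
  scheduled cue/doublet events, biphasic evoked responses, band-limited
  (20–450 Hz) background noise, saturating stimulus artifacts, volitional
  contamination, and trapezoidal force ramps at reaction-time latency —
  fully reproducible from a seed, with the drawn ground truth attached;
- **extraction**: epoching, artifact blanking, peak-to-peak R1/R2
  measurement with quality flags, recruitment curves with motor-threshold
  estimation, and force-onset reaction times;
- the **modulation statistics**: per-participant cell means (average of
  10 responses per CTI after a strict >2.5 SD outlier rule) paired against
  the 20-response resting control baseline; Shapiro–Wilk-routed paired
  Student's *t* or Wilcoxon signed-rank tests; Bonferroni correction within
  each muscle × movement × condition family; amplitudes expressed as
  percent of control (100% = no modulation); R2 filtering (dropped when
  R1 < 0.02 mV or R2 > R1) and R2/R1 ratios;
- **probability maps**: per muscle × CTI exceedance probabilities — the
  fraction of (conditioned, control) response pairs in which the
  conditioned response is higher (facilitation) or lower (inhibition) —
  with a dominance classification and heatmap/CSV rendering.

## Worked example

Thirteen synthetic participants prepare a plantarflexion on an auditory cue.
The generator facilitates the agonist (LSOL) R1 at late CTIs (factors 1.5,
2.0, 2.2 at 150/200/250 ms) and partially releases its post-activation
depression (R2/R1 rising from the resting 0.2 to 0.35–0.45); the antagonist
(LTA) is left unmodulated.

```r
library(semp)

p  <- default_protocol(movements = "plantarflexion", conditions = "auditory",
                       muscles = c("LSOL", "LTA"), rt_reps = 1, seed = 3)
em <- effect_model(
  modulation = effect_table(muscle = "LSOL", cti_ms = c(150, 200, 250),
                            value = c(1.5, 2.0, 2.2)),
  depression = effect_table(muscle = "LSOL", cti_ms = c(150, 200, 250),
                            value = c(0.35, 0.40, 0.45))
)
x   <- simulate_experiment(p, em, n_participants = 13, seed = 1)
mod <- analyze_modulation(x)
```

The agonist rows of `mod`:

```
 muscle cti_ms normalized_pct r2_r1_pct control_r2_r1_pct test_used p_adjusted    direction
   LSOL     50          101.9      20.3              19.8  t_paired   1.00e+00         none
   LSOL    100           98.4      20.0              19.8  t_paired   1.00e+00         none
   LSOL    150          153.4      34.7              19.8  t_paired   2.15e-06 facilitation
   LSOL    200          208.3      39.6              19.8  wilcoxon   1.22e-03 facilitation
   LSOL    250          218.6      44.5              19.8  wilcoxon   1.22e-03 facilitation
```

`normalized_pct` is the cell mean as percent of the participant-matched
resting baseline: the injected facilitation (150%, 200%, 220% of control)
is recovered, flagged significant after Bonferroni correction, and the
release of R2 depression shows up as R2/R1 ratios rising from the resting
~20% to 35–45%. The corresponding probability map saturates where the
effect separates the conditioned and control distributions:

```r
pm <- build_probability_map(x, "plantarflexion", "auditory")
```

```
 muscle cti_ms p_facilitation p_inhibition p_tie n_comparisons
   LSOL     50           0.52      0.47598     0          2540
   LSOL    100           0.49      0.50630     0          2540
   LSOL    150           0.93      0.06575     0          2540
   LSOL    200           1.00      0.00315     0          2540
   LSOL    250           1.00      0.00039     0          2540
```

Unmodulated cells sit near 0.5 (a conditioned response is as likely to beat
a control as not); facilitated cells approach 1. `render_outputs(mod,
list(pm), "out/")` writes the tables, a significance summary, and one
heatmap per map.

Signal-level work uses `simulate_session()` (rendered EMG/force traces),
`measure_session()` (R1/R2 extraction with artifact blanking),
`measure_reaction_times()`, and `write_session()`/`read_session()` for a
lossless CSV + JSON on-disk format.

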