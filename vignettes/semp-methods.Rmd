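---
title: "Models and methods behind semp"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind semp}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`semp` analyses paired-pulse transcutaneous spinal stimulation (TSS)
experiments: evoked motor potentials recorded from eight bilateral leg
muscles while a participant prepares or performs a movement, compared
against stimulation at rest. This vignette explains the generative model
used by the synthetic-session generator, the statistical pipeline, the
numerical conventions, and the design decisions taken where the procedure
was genuinely open.

```{r setup}
library(semp)
```

## The experimental model

A *session* is one continuous multi-channel recording: eight EMG channels
(left/right vastus lateralis, medial hamstrings, tibialis anterior,
soleus; mV) and one force channel (N), all sampled at 2000 Hz, plus an
event table. Stimulation is always a *doublet* — two pulses with a 50 ms
inter-stimulus interval. The response to the first pulse (R1) indexes
motor-pool excitability; the response to the second (R2) is suppressed at
rest by post-activation depression, so the per-pair ratio R2/R1 indexes
the state of the activated synapses.

The conditioning protocol (`default_protocol()`) per movement and cue
modality:

* ten fast cued contractions without stimulation, to measure the baseline
  reaction time from the force channel;
* ten resting control doublets at 5 s spacing (*pre* controls);
* ten conditioned doublets per condition-test interval (CTI) of 50, 100,
  150, 200, 250 ms between cue and first pulse, CTI order randomized,
  cues every 5–7 s with pseudorandom spacing;
* ten resting control doublets (*post* controls);
* for the isometric condition, ten doublets delivered 2 s into a
  maintained contraction.

Every analysis cell (muscle × movement × condition × CTI) is therefore
summarised from at most 10 responses and compared against a 20-response
resting baseline.

## The synthetic-session generator

No public recordings exist for this paradigm, so the generator is a
first-class, tested component: it produces sessions with exactly the
statistical structure the analysis assumes, and the drawn ground truth is
attached so that every downstream stage can be checked against what was
injected.

**Amplitude model.** For trial $i$ of a cell with modulation factor $f$
(relative to rest) and depression level $d$ (the expected R2/R1 ratio):

$$R1_i = A \, s_p \, f \, \varepsilon_{1i}, \qquad
  R2_i = R1_i \, d \, \varepsilon_{2i},$$

where $A$ is the muscle's resting mean amplitude (default 0.5 mV),
$s_p$ a per-participant lognormal scale (CV 0.3), and
$\varepsilon_{1i}, \varepsilon_{2i}$ independent lognormal factors with
mean 1 and coefficient of variation `amplitude_cv` (default 0.2).
Lognormal rather than Gaussian noise keeps amplitudes positive. R2 is
drawn *conditionally on the realized R1*: shared trial-to-trial
excitability is physiologically plausible (both responses ride on the same
motoneuron-pool state), it preserves $\mathbb{E}[R2] = \mathbb{E}[R1]\,d$,
and it makes the per-pair ratio estimator unbiased
($\mathbb{E}[R2_i/R1_i] = d$), which independent draws would not
($\mathbb{E}[R2/R1]$ would inflate by $1+\mathrm{CV}^2$).

**Signal model** (`simulate_session()`). Each EMG channel carries
band-limited Gaussian noise (white noise through a 4th-order zero-phase
Butterworth band-pass, 20–450 Hz — the recording bandwidth of typical
surface-EMG hardware — scaled to `noise_rms_mv`, default 0.01 mV); a
saturating 2 ms artifact at every pulse (default 5 mV) so that blanking
logic is genuinely exercised; and a biphasic evoked template at each pulse.
The template (`evoked_waveform()`) is one cycle of a damped sine — one
positive and one negative lobe — with onset latency 15 ms and duration
25 ms, values chosen to resemble posterior-root reflex responses in leg
muscles at this stimulation site; the sampled template is rescaled so its
realized peak-to-peak equals the drawn amplitude exactly, which is what
makes noiseless injected-vs-recovered tests exact. A configurable fraction
of movement trials (`contamination_prob`, default 0) receives a 0.6 s
volitional-EMG burst on the agonist channel. The force channel rises as a
*piecewise-linear* ramp (rise time 150 ms) to 20 N — nominally 5–10% of a
maximum voluntary contraction — one reaction time after each movement cue.
Reaction times are normal (defaults 210.2 ± 47.7 ms) truncated at zero by
redrawing. A linear onset, rather than a sigmoid, means the detection
threshold is crossed within a fraction of a millisecond of the true onset,
so onset-detection bias stays well below one sample; a smooth sigmoid
start would add a noise-dependent detection latency of several
milliseconds.

**What the generator does and does not emulate.** It reproduces the trial
bookkeeping, CTI-dependent amplitude modulation, R2 depression and its
release, amplitude variability within and between participants, recording
noise, artifacts, and reaction-time variability. It does *not* model
afferent/motoneuron biophysics, latency shifts with state, waveform-shape
changes, electrode geometry, fatigue, or habituation. Passing tests
therefore certify the *pipeline* — extraction, filtering, statistics,
maps — under realistic amplitude statistics, not the physiology of real
recordings.

## Extraction conventions

* Times are stored in seconds; sample indices are derived by
  nearest-sample rounding, and epoch windows are half-open
  `[t0+start, t0+end)`.
* Response windows are 5–45 ms after each pulse (the paired-pulse interval
  caps the usable window at 50 ms minus the blanking margin), and samples
  within 0–3 ms of any pulse are blanked before the peak-to-peak is taken.
  All three are configurable via `measure_settings()`.
* Quality flags: R1 below the 0.02 mV response floor; R2 > R1 (suggesting
  volitional contamination).
* The outlier rule is a strict `> 2.5` sample-SD exclusion, with mean and
  SD computed over all submitted values including the candidate, applied
  in a *single pass* (not iterated on the retained set); with fewer than 3
  values nothing is excluded. A value exactly at 2.5 SD is kept.
* The motor threshold is the lowest sampled intensity whose mean R1
  reaches the 0.02 mV floor with all higher sampled intensities also at or
  above it — the floor is the only amplitude criterion the procedure
  defines, so it is reused rather than inventing a second constant.
* Force onset: first crossing of baseline mean + 3 baseline SD (500 ms
  pre-cue baseline) sustained for ≥ 25 ms. With zero baseline noise the
  threshold degenerates to a strict crossing of the baseline mean, giving
  onset errors of at most one sample.

## The statistical pipeline

The unit of analysis is the participant: each participant contributes one
cell mean (≤ 10 responses after outlier exclusion) paired with their own
baseline (mean of the pooled 20 pre/post controls after outlier exclusion
of the pool). Normalized amplitude is reported as the ratio of the group
mean cell amplitude to the group mean baseline, × 100 — the ratio of means
rather than the mean of per-participant ratios, because it is less biased
by baseline sampling noise and participant amplitude scales largely cancel
between numerator and denominator; either convention is invariant to
rescaling a session.

Normality of the paired differences is tested with Shapiro–Wilk; at
p > 0.05 a two-tailed paired Student's *t* test is used, otherwise a
two-sided Wilcoxon signed-rank test (exact null distribution for small
samples without ties, normal approximation with correction otherwise —
`stats::wilcox.test`'s convention). Degenerate inputs are defined away
rather than left to error: all-zero differences return p = 1; constant
non-zero differences cannot be assessed by Shapiro–Wilk and are routed to
the Wilcoxon branch.

Bonferroni correction is applied within each muscle × movement × condition
family — the five CTIs of that family — the most conservative family
consistent with per-CTI reporting; the family size is configurable.
Direction labels: *facilitation* if significant and above 100% of control,
*inhibition* if significant and below.

R2 responses are removed (R1 kept) when R1 < 0.02 mV or R2 > R1; ratios
are averaged per participant and cell and reported alongside the same
participant-set's control ratio.

## Probability maps

For each cell, the conditioned R1 values are compared against the block's
control values after outlier exclusion of each set. The default *pairwise*
interpretation counts, over all (conditioned, control) pairs, how often
the conditioned value is strictly higher (facilitation) or strictly lower
(inhibition), divided by the number of pairs — the Mann–Whitney count
normalised to the common-language effect size. An alternative
*exceeds-all* interpretation (a conditioned response beating *every*
control, over the number of conditioned responses) is available via
`mode = "exceeds_all"`; the pairwise reading is the default because a
"total number of comparisons" denominator most naturally counts pairs.
Ties are tallied separately (strict inequalities, no 0.5 split); with
continuous amplitudes they have probability zero, and
`p_facilitation + p_inhibition + p_tie` sums to 1 exactly (the tie share is
stored as the complement). With several participants, comparisons are made
within participant and pooled by summing counts and denominators. The
isometric condition forms a single extra column beside the CTIs.
`classify_modulation()` labels each cell by the larger probability,
*balanced* on an exact tie.

## Numerical and storage choices

Sessions are stored as a JSON manifest plus wide CSV signal and event
tables. Doubles are written with 17 significant digits and parsed with a
correctly rounded reader, so a write/read round trip reproduces every
sample bit for bit; this is what makes the determinism guarantee (same
protocol, effect model, and seed → byte-identical session directories)
testable at the file level. Validation (`validate_session()`) returns
machine-readable violation codes rather than throwing, and tolerates a
doublet interval error of one sample (0.5 ms at 2000 Hz).

## Problem sizes used by the test suite

The Monte-Carlo checks run at the design's own sizes — 13 participants,
10 repetitions per CTI, 20 controls — with replicate counts chosen for
stable estimates: 500 replicate experiments for type-I error calibration,
200 for effect recovery, 200 trials for reaction-time recovery, and 40
replicates for probability-map calibration, with single-muscle or
single-CTI protocols where the quantity under test does not depend on the
grid size.

## Known limitations

* The strict 2.5 SD outlier rule interacts with skewed amplitude
  distributions: it trims the upper tail more often in larger pools, so
  the 20-response baseline is trimmed slightly more than a 10-response
  cell. Under lognormal trial noise at CV 0.2 this biases normalized
  amplitudes upward by a fraction of a percent — negligible against the
  reported effects (which reach several hundred percent of control), but
  detectable in high-replicate simulations. In recordings whose outlier
  incidence is at the per-mille level the effect vanishes.
* Ties in the Wilcoxon branch force the normal approximation; with
  continuous amplitude data this is immaterial.
* Resting mean amplitudes per muscle and their variability are generator
  stand-ins, not empirical claims; absolute amplitudes should not be
  compared against real recordings, only relative (percent-of-control)
  quantities.
* The generator's evoked template has fixed latency and shape; analyses
  that depend on latency or morphology (e.g., reflex vs direct-response
  discrimination) are out of scope.
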