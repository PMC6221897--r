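---
title: "Single-trial phase-locking networks: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Single-trial phase-locking networks: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plvnet)
```

## The model

`plvnet` treats every intracranial contact as a node of a weighted functional
network that is rebuilt on **every trial**. The signal chain is:

1. **Epoching.** Trials are cut around cue onset (cue at t = 0, half-open
   sample bins), keeping only trials whose instructed delay matches the
   analysis delay (default 1500 ms). A buffer (default 0.5 s per side) is kept
   for filtering and trimmed before any feature is computed. Trials with a
   keypress at or before the go signal are excluded up front.
2. **Phase extraction.** A zero-phase windowed-sinc FIR band-pass (70–100 Hz
   by default) followed by the Hilbert analytic signal gives instantaneous
   phase per trial, channel and sample.
3. **Connectivity.** In each 500-ms analysis bin the phase-locking value
   between channels i and j is the magnitude of the time-averaged unit phasor
   of their phase difference over the T samples in the bin. PLV is computed
   per trial (never averaged over trials), is symmetric by construction, and
   the diagonal is set to 0 so strength sums need no self-edge correction.
4. **Network statistics.** Nodal strength is the mean edge weight per node
   (`s_k = Σ_j w_kj / (N−1)`); global strength is its mean over nodes, which
   equals the average edge weight over all pairs. Communicability is
   `Qexp = exp(D^{-1/2} A D^{-1/2})` with D the diagonal of row sums — the
   degree normalisation standard for weighted networks — computed exactly via
   the eigen-decomposition of the symmetric normalised matrix; nodal
   communicability is the row mean excluding the diagonal.
5. **Spectral baselines.** HFA is the analytic-amplitude band power (mean
   squared amplitude / 2, the time-averaged squared signal of a narrowband
   input), z-scored across trials within each (bin, channel) using the sample
   standard deviation; spectral tilt is high-band minus low-band (3–12 Hz) z.
6. **Statistics.** Trials are partitioned into reaction-time terciles
   (floor(n/3) per extreme group; ties at a boundary resolved
   chronologically). Bin-wise fast/slow contrasts of global strength use the
   Wilcoxon rank-sum normal approximation with tie-corrected variance and
   continuity correction, against a Bonferroni threshold over the four bins
   (α/4 = 0.0125 at α = 0.05). Per-node contrasts use Welch t-tests.
   Single-trial features are related to RT by Pearson correlation.
7. **Decoder.** A linear-kernel SVM (cost 1) on two features — pre-cue global
   strength and the pre-cue communicability of a designated channel — with
   stratified 10-fold cross-validation; features are standardised with
   training-fold statistics only, and decision values are pooled across folds
   before the AUC is computed. Significance comes from a permutation null in
   which labels are regenerated as fair Bernoulli draws (a label-permutation
   option preserves class balance) and the AUC is recomputed; the p-value uses
   the add-one rule (1 + #{null ≥ observed}) / (1 + n_perm).

## What the synthetic generator emulates

The package ships a session generator because the analysis needs a ground
truth: a recording in which we *know*, per trial, how strongly the channels
were phase-coupled before the cue and how that coupling relates to behaviour.

Each channel is the sum of three parts, in µV:

- **1/f background** (spectral exponent 1, RMS 1) — the broadband field
  potential floor;
- a **low-band oscillation** (7.5 Hz, amplitude 2) so the 3–12 Hz baseline
  band contains real signal;
- a **gamma oscillation** at the band centre (85 Hz) whose phase is a
  trial-common oscillator plus per-channel von Mises jitter. The jitter is
  redrawn every 25 ms (about two carrier cycles): phase slips in band-limited
  field potentials happen at the cycle timescale, and holding the jitter at
  that timescale keeps the injected concentration from being averaged away by
  the analysis band-pass. Gamma amplitude is drawn per trial and channel from
  a lognormal (meanlog log 2, sdlog 0.4), independently of the coupling, so
  power-based features (HFA, tilt) and phase-based features are dissociable by
  construction.

The coupling parameter κ ∈ [0, 1] is drawn uniformly per trial. By default it
maps to the jitter concentration through the inverse of the squared von Mises
mean resultant length, `c = A1⁻¹(√κ)`, so that the **population pairwise PLV
equals κ**. A linear map (`concentration = κ · κ_max`) is available via
`phase_jitter_map = "linear"`, but it is a poor control dial: its PLV response
`A1(κ·20)²` saturates by κ ≈ 0.3, and κ = 1 never reaches PLV 1. The coupling
state onsets 100 ms before the pre-cue window so that filter bleed from the
uncoupled inter-trial period does not contaminate the first analysis bin.

Reaction times follow `RT = 450 − 200·κ + N(0, 100)` ms, floored at 100 ms.
With κ uniform this puts the true κ–RT correlation near −0.5, a realistic
single-session effect size for this kind of task. Crucially, κ applies only to
the −500..0 ms pre-cue window; the delay-period coupling is drawn
independently of RT, so **only pre-cue features carry behavioural signal** —
the pipeline's bin-wise specificity is testable against that construction.
Delays are 500 or 1500 ms with equal probability; only the generated event
table and EDF file leave the generator, exactly as for a recorded session.

What the generator does **not** emulate: biophysical neural-mass dynamics,
line noise or artifacts, heterogeneous network topology (every channel is
coupled to the same common oscillator, so there are no privileged hubs),
non-stationary amplitude dynamics, or volume conduction. Passing tests
therefore show that the estimators recover injected synchrony structure and
behave correctly under a realistic noise floor — not that any particular brain
region behaves this way.

One consequence of the homogeneous topology is worth spelling out: the degree
normalisation makes Qexp invariant to uniform scaling of all edge weights, so
in a network where coupling rises and falls *globally*, nodal communicability
carries much less reaction-time signal than strength does. In real recordings
the interesting Qexp signal comes from topological reconfiguration, which this
generator deliberately does not inject; the decoder's synthetic-data
performance is therefore driven mostly by the strength feature.

## Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| `gamma_band` | 70–100 | Hz | high-gamma analysis band; edges well below Nyquist at ≥ 250 Hz sampling |
| `low_band` | 3–12 | Hz | baseline band for spectral tilt, one band (not split theta/alpha) |
| `bins_ms` | 4 × 500 ms | ms | pre-cue, early/mid/late delay; contiguous, half-open |
| `window_s`, `buffer_s` | (−0.5, 1.5), 0.5 | s | epoch plus filter buffer, trimmed after phase extraction |
| `delay_filter_ms` | 1500 | ms | only long-delay trials give all four bins |
| `kappa` range | U(0, 1) | — | per-trial coupling; population pre-cue PLV equals κ |
| `rt_intercept/slope/noise` | 450 / 200 / 100 | ms | linear monotone link, true κ–RT correlation ≈ −0.5 |
| `jitter_hold_ms` | 25 | ms | cycle-scale phase slips; survives the band-pass |
| decoder `k`, `n_perm` | 10, 1000 | — | stratified folds; add-one permutation p |

## Numerical choices and degenerate inputs

- **FIR design.** Hamming windowed-sinc, order from the 3.3/Δf rule with a
  transition width of 25% of the lower band edge, applied forward and
  backward by FFT convolution (zero phase). For the 3–12 Hz band on short
  epochs the rule would demand more taps than samples; the order is capped at
  the epoch length with a warning (the transition band widens accordingly).
- **Band power.** Defined from the analytic amplitude (mean |a|²/2), not a
  periodogram, consistent with the Hilbert pipeline; no log transform before
  z-scoring by default (`log_power` switch available).
- **Zero variance.** Across-trial z-scores of constant cells are set to 0 with
  a warning; Welch contrasts of channels constant in both groups report
  t = 0, p = 1 with a warning; a constant correlation feature is an error.
- **Isolated nodes.** Degree normalisation floors zero row sums at 1e-12, so
  an empty network has Qexp = I.
- **Ties.** Tercile boundaries resolve RT ties chronologically (earlier trial
  takes the lower-rank class); the rank-sum variance is tie-corrected.
- **Sliding bins.** The "sliding" computation is exposed as arbitrary
  (start, end) bin rows; the default is the four contiguous non-overlapping
  bins actually analysed.
- **Strength conventions.** Nodal strength defaults to the mean-edge
  convention so that global strength is simultaneously "mean nodal strength"
  and "mean pairwise edge weight"; `convention = "sum"` gives plain row sums
  (the two differ by the factor N−1).
- **Decoder orientation.** The SVM decision value is sign-normalised so that
  larger means "fast" before pooling, making the null AUC symmetric at 0.5.
- **Reproducibility.** `simulate_session()` is bit-reproducible from its seed;
  `permutation_test()` from (seed, n_perm, k); the pipeline from the run seed.

## Design decisions that were genuinely open

- **Welch rather than pooled t** for per-node contrasts: with unequal
  variances the Welch–Satterthwaite df drops below n₁+n₂−2, which is the
  conservative choice when group variances are not known to match. The df is
  reported per channel rather than assumed.
- **Permutation null generates labels** (Bernoulli ½) rather than permuting
  them, matching the stated procedure of randomly generated labels; the
  permutation variant is exposed for users who want class balance preserved.
- **AUC from pooled cross-fold decision values** rather than per-fold AUC
  averaging: with ~38 trials a 10-fold split leaves ~4 test trials per fold,
  where per-fold AUCs are extremely noisy.
- **One-sided tests require an explicit direction**; nothing is inferred from
  the data.
- **No correction across the per-node tests** by default (the bin-wise family
  of four is Bonferroni-corrected); the output flags this so users can apply
  their own channel-wise correction.

## Problem sizes used by the test suite

The suite exercises the estimators at reduced but statistically meaningful
sizes: oracle equivalence on 4-channel/64-sample tensors and 6-node networks;
type-I calibration on 500 simulated null sessions of 8 channels × 30 trials at
500 Hz; parameter recovery and bin specificity on 20 sessions of 16 channels ×
60 trials with the default effect size; decoder calibration on 120 permutation
tests of 24 trials. The acceptance script runs one study-scale session
(32 channels, 114 trials, 512 Hz). These sizes were chosen so the full battery
demonstrates calibration and recovery with tight Monte-Carlo error while
remaining comfortably reproducible on a laptop.

## Known limitations

- The EDF writer/reader supports the plain 16-bit EDF profile with a single
  shared sampling rate — sufficient for round-tripping sessions, not a general
  EDF+ implementation.
- PLV is the only connectivity estimator (no PLI/wPLI/coherence); volume
  conduction is not addressed, consistent with the intracranial setting.
- The permutation decoder refits the SVM for every draw; at n_perm = 1000 and
  ~40 trials this costs seconds, but it scales linearly in n_perm.
- The designated communicability channel is selected on the same trials used
  by the decoder (maximum fast-slow contrast), mirroring the single-session
  analysis it implements; out-of-sample channel selection would need a held-out
  session.
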