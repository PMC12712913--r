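---
title: "Methods: synthetic LFP sessions, spectral statistics, evoked-potential and dosimetry models in sonolfp"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: synthetic LFP sessions, spectral statistics, evoked-potential and dosimetry models in sonolfp}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sonolfp)
```

`sonolfp` analyzes local field potentials (LFPs) recorded during focused
ultrasound neuromodulation of genetically sensitized neurons (sonogenetics
with bacterial mechanosensitive channels). This vignette documents the
models, the tunable parameters, the numerical choices, and what the
synthetic-data generator does and does not emulate.

## The recording and stimulation model

A recording is a channels × time voltage matrix in µV with a sampling rate
and a list of stimulation onset times (seconds, 0-based, rising edges of the
sync pulse). The pulsed-ultrasound protocol is parameterized by the
fundamental frequency (FF, MHz), pulse repetition frequency (PRF, kHz), duty
cycle (DC, fraction), tone burst duration (TBD, ms), sonication duration per
stimulus (SD, s), inter-stimulus interval (ISI, s) and phase length (s).
The defaults are the standard sonogenetics paradigm: FF 1.0 MHz, PRF
1.0 kHz, DC 50%, TBD 0.5 ms, SD 0.3 s, ISI 3 s, 150 s phases, with the
empirical calibration table 100 → 0.15, 250 → 0.25, 400 → 0.35
(Ispta mW/cm² → peak negative pressure MPa). `validate_protocol()` enforces
the identity DC = TBD × PRF to 10⁻⁹; inconsistent configurations are
rejected rather than silently renormalized.

Onsets are defined on rising edges. Because the sync line pulses at the PRF
*within* each 0.3 s burst, `extract_sync_onsets()` merges edges closer than
a refractory window, defaulting to the SD (0.3 s), so each sonication is one
onset.

## Synthetic sessions

The generator produces recordings with the statistical structure the
analysis assumes, so pipeline accuracy can be quantified by parameter
recovery.

**Background.** Spontaneous LFP is a sum of five independent band-limited
Gaussian processes, one per canonical band (delta 0.5–4, theta 4–8, alpha
8–12, beta 12–30, gamma 30–100 Hz). Each band is synthesized in the Fourier
domain with complex Gaussian coefficients on its own (disjoint) frequency
support and rescaled to its exact target variance
`band_fraction × total_rms²`. Disjoint supports make the bands exactly
orthogonal in the sample, so the realized relative power of a generated
session equals the specified fractions up to filtering and windowing
effects — the generator directly parameterizes the statistic the spectral
module estimates. We chose this over autoregressive fits because band-wise
relative power is the only spontaneous-activity statistic the study design
reports; an AR background would add shape assumptions the analysis never
exploits. Per-realization exact scaling (rather than random variance around
a target) is deliberate: the recovery benchmarks then measure estimator
bias, not generator luck.

**Evoked responses.** The ultrasound-evoked potential is a biphasic
template — a negative Gaussian trough (FWHM `width`, default 20 ms) with a
smaller (30%), broader positive rebound — scaled so the trough magnitude is
exactly `n1_amp` µV at `latency` ms after the onset. Trial-to-trial
variability enters as multiplicative amplitude jitter (SD fraction
`jitter_amp`, default 0.05) and additive latency jitter (SD `jitter_lat`,
default 5 ms). The template shape is a modeling choice: the literature
shows, but does not parameterize, UEP waveforms; only the trough amplitude
and latency are quantified downstream, and those are exact by construction.

**Stimulation power gain.** The stimulation phase's background is scaled by
`sqrt(1 + stim_power_gain)`, producing a broadband total-power change of
exactly `stim_power_gain` (e.g. 0.212 → +21.2%). The mechanism behind the
in-vivo power change is not disclosed by the study design, so a broadband
gain — the least structured choice consistent with a "total power"
statistic — is used.

**Line noise and artifacts.** 50 Hz mains plus odd harmonics (150, 250,
350 Hz) are added as fixed-amplitude sinusoids with seeded random phases,
defaulting to a 10 µV fundamental halving per harmonic. The non-biological
ultrasound artifact is an exponentially decaying 80 Hz oscillation
(`artifact_template()`), standing in for the transient identified in
post-mortem controls; it doubles as the matching template for rejection.

**Presets.** `load_preset()` returns specs for the four groups (CON,
MscL-G22S, MscL-G22N, MscS) at 100/250/400 mW/cm². Published group summary
values are used verbatim where they exist (the G22N band fractions, which
conveniently sum to exactly 1; the per-intensity stimulation gains; the
evoked amplitudes 36.2/40.16/24.2 µV at 400 mW/cm²). The remaining entries
are fixed representative values for isoflurane-anesthetized rat hippocampus:
delta-dominated fractions for the unreported groups, evoked latencies
decreasing with intensity (120 → 80 ms for G22S), 20 ms trough width, and a
50 µV total background RMS.

**UEP-mode background (a deliberate SNR choice).** Evoked-trial sessions
(`mode = "uep"`) use a 6 µV background instead of 50 µV. Per-trial trough
detection of a 40 µV N1 against 50 µV of broadband LFP (dominated by slow
delta fluctuations that survive any causal-free filtering) is impossible for
any detector — the in-vivo analog relies on referenced, artifact-cleaned
evoked recordings whose effective noise at the trough is far below the raw
LFP RMS. At 6 µV the significance floor (3 × pre-onset SD ≈ 18 µV) sits
safely below the 24–40 µV preset amplitudes while still exercising the
detector against realistic noise. This constant was chosen from this noise
analysis when the generator was designed, not adjusted afterwards.

**What the generator does not emulate:** 1/f spectral slopes within bands,
non-sinusoidal oscillation shape, cross-frequency coupling, non-stationary
anesthesia depth, electrode drift, spikes, and channel-to-channel
covariance. Passing recovery benchmarks therefore demonstrates estimator
correctness on stationary band-structured signals, not robustness to every
property of real recordings.

## Preprocessing

The cleaning chain is: remove DC, notch 50/150/250/350 Hz (biquad IIR, Q =
30 — no notch design is prescribed by the study, and Q = 30 gives a −3 dB
width of ~1.7 Hz at 50 Hz, narrow enough to spare gamma), then Butterworth
bandpass 0.5–100 Hz of prototype order 2. Filtering is zero-phase
(forward–backward) by default: evoked latencies are a primary outcome, and
causal filtering would bias the trough later by the group delay. The price
is a doubled effective order (−6 dB rather than −3 dB at the band edges);
`filter_spec(zero_phase = FALSE)` restores single-pass causal behavior.

Epochs span −1 to +2 s around each onset; trials extending past the
recording edges are dropped, not padded. Baseline correction subtracts the
trial mean over −1–0 s. Artifact rejection slides the template over the
0–0.5 s post-onset window and flags trials whose maximal normalized
(Pearson) cross-correlation reaches `rho_min` (default 0.8; the quantitative
matching criterion is not specified by the source methodology, so the
threshold is exposed and the flag rate is reported).

## Spectral statistics

Welch PSD: Hanning window, 50% overlap, one-sided density scaling, segments
demeaned. **Segment length is 8 s** (0.125 Hz resolution). This was chosen
after quantifying edge bias at the delta band's 0.5 Hz lower bound: with 2 s
segments (0.5 Hz resolution) the combination of segment demeaning, window
smearing below 0.5 Hz and the half-bin trapezoid edge removes ~10% of
delta-band power, biasing delta relative power by ~3 percentage points on
delta-dominated signals; at 8 s the bias falls to ~1.5 points, within the
package's ±3-point recovery goal. The residual deterministic loss is the
zero-phase 0.5 Hz high-pass edge acting on the lowest ~0.5 Hz of the delta
band; it is visible as recovered delta RP of ≈ 58.7% for a 60.29% preset.

Band powers integrate the PSD by the trapezoidal rule over contiguous band
edges, so band powers sum exactly to the 0.5–100 Hz total and relative
power sums to 100% by construction. `total_power_db` uses a configurable
reference (default 1 µV²); absolute dB values are therefore not comparable
across conventions, and the package treats them as descriptive only. The
theta/gamma ratio is computed per recording and averaged across subjects
(mean of ratios): a ratio of group-mean RPs is not equal to the mean of
per-subject ratios, and the per-subject form is the one that supports
subject-level inference.

The stimulation-normalized power change is
`(P_stim − P_pre) / P_pre × 100` on per-phase Welch total power of the
filtered signal (and per band). Because it is a ratio, the deterministic
filter losses cancel, and the generator's gain is recovered essentially
unbiased (21.2% preset → 20.9–21.9% across seed blocks).

## Evoked-potential quantification

N1 is the *first* local minimum of the (optionally smoothed, default 5 ms
moving average) trace within 0–500 ms post-onset whose depth reaches a
significance floor of 3 × the pre-onset SD. The first-minimum rule is
enforced regardless of later, deeper troughs. Amplitude is read from the
unsmoothed trace at the smoothed-trace trough index: smoothing stabilizes
the pick under noise without attenuating the reported amplitude, and a
noiseless injected trough is recovered exactly. If the floor degenerates to
zero (noiseless baseline), 5% of the largest in-window excursion is used so
numerical ripple is not reported as a response. Detection is per-trial
(trial-level n is the reported unit downstream); non-responses are excluded
from amplitude/latency means and reported as a rate. The ~1.2 µV shortfall
of recovered versus injected amplitude (38.8 vs 40.16 µV) is the bandpass
acting on the 20 ms trough — a property of the measurement chain the
benchmark is designed to expose, and well within the ±2 µV recovery goal.

## Dosimetry and thermal model

Closed forms: DC = TBD × PRF; Ispta = Isppa × DC; MI = PNP/√FF (MPa, MHz),
with a warning above the regulatory limit of 1.9. The intensity↔pressure
calibration is an empirical lookup table: the measured pairs are not
consistent with the plane-wave relation I = p²/(2ρc) (focused transcranial
fields are not plane waves), so deriving one from the other would be wrong;
a `planewave_intensity()` converter is provided separately and labeled
approximate.

The thermal estimate is a zero-dimensional Pennes-style model: during each
sonication the focus heats at dT/dt = 2αI/(ρc) − ΔT/τ, and relaxes with the
perfusion time constant τ between stimuli. I is the temporal-average
intensity *during* sonication — the calibrated Ispta, which already
averages over the within-burst duty cycle. Defaults are standard
brain-tissue values: α = 0.04 Np/cm at 1 MHz, ρ = 1040 kg/m³, c = 3630
J/kg/K, τ = 60 s; all configurable, and documented here as
literature-standard rather than study-specific (the source supplementary
formulation is not reproduced in its main text). The trace is evaluated
analytically segment by segment (piecewise-constant heating has an exact
exponential solution), so the integrator agrees with the no-cooling closed
form 2αIt/(ρc) to numerical precision. For 50 pulses at 400 mW/cm² the
model gives a maximum rise of ≈ 0.044 °C, comfortably below the 0.2 °C
safety bound.

## Behavioral scoring and group statistics

Y-maze spontaneous alternation scores windows of three consecutive arm
entries visiting three distinct arms: 100 × alternations / (entries − 2).
Forced-swim immobility clips bouts to the last-4-minutes window (120–360 s)
and reports bout count and summed duration. Zone summaries merge
overlapping bouts (interval union) before counting entries.

`compare_groups()` implements the gated battery: Shapiro–Wilk per group at
α = 0.05; if *any* group fails, the whole measure switches to
Kruskal–Wallis with two-sided Dunn post-hoc comparisons versus control,
otherwise one-way ANOVA with Dunnett's test. The any-group rule is the
conservative reading of an under-specified gate ("depending on normality
and homogeneity"); Levene's homogeneity test is computed but advisory only.
Dunn p-values are Bonferroni-adjusted over the three versus-control
comparisons — the multiplicity adjustment is not named in the source
convention, and Bonferroni over the vs-control family is the conservative
default. Dunn z statistics use the standard tie correction. Note the Dunn
p-value is asymptotic-normal: on small samples it tracks an exact
permutation oracle to within a few hundredths, which is the agreement level
the test suite asserts (tolerance 0.04 at n = 8 per group).

## Problem sizes and determinism

The recovery benchmarks use the study's own scales: 150 s phases at 1 kHz
synthesis (the LFP band ends at 100 Hz; 20 kHz acquisition is supported but
adds nothing for ≤100 Hz analyses), 5 independent seeds for spectral
recoveries, 50 trials for evoked recovery, 50 pulses for the thermal bound,
1000 null simulations for the type-I calibration and 10⁴ permutations for
the Dunn oracle. Every stochastic routine takes an explicit seed and
restores the caller's RNG state.

## Known limitations

- The generator's stationary band-structured background understates real
  LFP complexity (see above); recovery results bound estimator bias, not
  field performance.
- Absolute dB totals depend on an arbitrary reference and are not
  benchmarked.
- The artifact template and its 0.8 correlation threshold stand in for an
  unspecified matching procedure; flag rates should be inspected, not
  trusted blindly.
- The thermal model is zero-dimensional: no conduction, no acoustic field
  geometry. It is a safety-margin estimate, not a simulation.
- Behavioral inputs are pre-scored event tables; video tracking is out of
  scope.
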