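---
title: "Methods: the psgpharm sleep-pharmacology analysis pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the psgpharm sleep-pharmacology analysis pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(psgpharm)
```

psgpharm implements the quantitative workflow of a rodent
sleep-pharmacology experiment in which a REM-sleep-promoting drug is
characterized by (i) 24 h EEG/EMG polysomnography under a 12 h
light/dark cycle, (ii) single-unit recordings of locus ceruleus
norepinephrine (LC-NE) neurons under cumulative intravenous dosing,
(iii) noncompartmental plasma pharmacokinetics, and (iv) qPCR
quantification of a receptor knockdown. This vignette documents the
models, conventions and numerical choices, and what the synthetic-data
generators do and do not emulate.

## Coordinate and phase conventions

All within-recording times are seconds from recording start. Zeitgeber
time (ZT, hours since lights-on; lights on at 7:30 A.M. in the
emulated colony) is carried as metadata and never baked into sample
indices. The light (inactive) phase is ZT `[0, 12)`, the dark (active)
phase ZT `[12, 24)`; a bout spanning the boundary belongs to the phase
containing its first epoch — a deterministic, order-free rule.

## Vigilance scoring

Recordings are analyzed in fixed 10 s epochs. Scoring uses two feature
families per epoch: EEG band powers from a Welch periodogram (delta
and theta, with the theta/delta ratio as the REM signature) and the
EMG root-mean-square as muscle tone. The rule cascade is:

1. EMG RMS above the recording's `emg_wake_quantile` quantile
   (default 0.60) scores **WAKE** — muscle tone beats any EEG pattern;
2. otherwise theta/delta above `theta_delta_rem_threshold` (default 2)
   *and* EMG below the `emg_atonia_quantile` quantile (default 0.25)
   scores **REM**;
3. otherwise **NREM**.

Thresholds are quantiles of the recording being scored, not absolute
amplitudes, because EMG gain depends on electrode impedance and
amplifier settings and does not transfer between animals or rigs. The
practical consequence is that `emg_wake_quantile` should approximate
one minus the expected wake fraction of the recording: the quantile
estimate then falls in the gap between the NREM and WAKE tone
clusters. With the default 0.60 (appropriate for recordings that are
roughly 40% wake) applied to a recording with a substantially
different wake fraction, the threshold lands inside one of the
clusters and splits it; the parameter-recovery experiments in the test
suite therefore calibrate the quantile to the simulated recording's
occupancy, which is the recommended usage. An optional smoothing pass
(`smooth_hypnogram()`) reassigns runs shorter than
`smoothing_min_bout_epochs` to the preceding state until a fixed
point; it never increases the bout count.

## Spectra and relative band power

Per-epoch spectra are Welch estimates: Hann-windowed segments of
`2 * fs` samples (0.5 Hz bin width) at 50% overlap, averaged within
the epoch, one-sided, truncated to `[0, 64)` Hz (128 bins). Welch
averaging was preferred over a single FFT of the whole epoch for its
variance reduction; a 10 s epoch at 128 Hz yields 9 averaged segments.

Band percentages follow the total-power normalization: each epoch's
total power is the sum of the fifty 0.5 Hz bins with
`0 < f <= 25` Hz, and a band's relative power is 100 times its bin sum
over that total. Two deliberate conventions:

* the DC bin is excluded from the total — amplifier offset is not
  physiology — and the 25.0 Hz bin closes the set at exactly 50 bins,
  so per-epoch relative powers over those bins sum to exactly 100 and
  a flat spectrum puts `100 * 7/50 = 14%` into delta;
* band edges are half-open `[lo, hi)` and configurable, with rodent
  defaults delta `[0.5, 4)`, theta `[4.5, 8.5)`, sigma `[10, 14)` Hz.
  No claim is made that these edges reproduce any particular published
  band analysis, since band edges are rarely printed; every band-level
  result in this package is defined relative to its own configured
  edges.

Normalization makes the output invariant to global gain (gauge
invariance), which is what permits pooling across animals.

## Sleep architecture and the fragmentation index

Bouts are maximal runs of one state; architecture metrics are pure
functions of the hypnogram, with no minimum bout length (any
suppression of short bouts belongs to scoring, so that architecture
numbers remain reproducible from a stored hypnogram alone). The sleep
fragmentation index (SFI) is the number of awakenings — transitions
NREM→WAKE or REM→WAKE — divided by total sleep time in the window,
reported in awakenings per hour of sleep. Units are fixed because a
bare ratio is ambiguous across window lengths; per-hour is the common
convention in the sleep literature. NREM↔REM transitions do not break
"sleep", and the index is invariant under splitting epochs within
bouts.

## LC-NE burst analysis

Bursts follow the classical two-threshold interspike-interval
criterion: a burst is a train of at least two spikes whose opening ISI
is strictly below 80 ms and which extends while subsequent ISIs are at
most 160 ms. Boundary semantics are fixed as `< 80` (strict, per the
criterion's wording) and `<= 160` (inclusive); the detection is a
greedy left-to-right scan, a spike belongs to at most one burst, and a
new burst may open on the spike immediately after a closed one. The
same semantics are used by the independent brute-force checker in the
test suite, which enumerates candidate runs wholesale and resolves
overlaps left-to-right; the two agree burst-for-burst on a thousand
random trains spanning the LC tonic range (0.5–7.5 Hz).

Dose blocks are half-open `[start, end)` so spikes are never double
counted. Block firing rates are whole-block counts over duration
(no sliding window); the "per 200 s" burst count is a linear
normalization. Rates are expressed as percent of the baseline
(vehicle) block, which makes them scale-free: superposing two
independent copies of a train leaves the expected percentage
unchanged.

The five burst metrics are bursts per 200 s, percent of spikes in
bursts, mean spikes per burst, mean intra-burst ISI, and mean burst
length. The intra-burst ISI metric is the mean over bursts of each
burst's own mean ISI (not the pooled ISI mean); with no bursts the
count metrics are 0 and the means are reported missing, and with no
spikes at all every metric is missing.

## Noncompartmental pharmacokinetics

`nca()` takes Cmax and Tmax directly from the observed points, fits
ordinary least squares to log concentration over a terminal subset,
and reports `lambda_z` (minus the slope), `t1/2 = ln 2 / lambda_z`,
and the linear-trapezoid AUC to the last point. The default terminal
rule is the last three points: with a sparse four-point design this is
the smallest subset that still averages over the terminal noise, and a
two-point rule is far too sensitive to a single concentration.
An adjusted-R² scan over post-Tmax suffixes is available
(`best_adj_r2`), with ties broken toward more points. Log-down
trapezoids and weighted regression are deliberately not offered: with
so few points the method choice would dominate the answer, so the
simplest, most transparent estimator is used and documented.

## qPCR quantification and statistics

Relative expression uses the ddCt construction: per sample,
`dCt = Ct(target) - mean Ct(references)`; per group,
`ddCt = dCt - mean dCt(control)`; fold change `= 2^-ddCt`. Multiple
reference genes are combined by the arithmetic mean of their Ct
values, equivalent to the geometric mean of their expression — the
conventional choice when no combination rule is stated. The
construction is invariant to plate-wide Ct offsets.

The statistical battery matches the study design: D'Agostino–Pearson
omnibus normality (implemented from the published skewness and
kurtosis normal approximations, cross-checked against an independent
implementation; it requires n ≥ 8), one-way ANOVA with an optional
subject stratum for repeated measures, a mixed two-way ANOVA with a
between-subject treatment factor and a within-subject phase factor,
pooled-variance two-tailed t tests (first argument minus second), and
Bonferroni adjustment `min(1, m p)` with an explicit family size. No
sphericity correction is applied: the within factor has two levels,
for which none is needed. The mixed design reproduces the
degrees-of-freedom structure of a 4-group, 42-animal experiment —
between df `(3, 38)` — which is the design the battery is meant to
serve. Degenerate inputs follow fixed conventions rather than
erroring where a convention is defensible: identical constants give
`F = 0, p = 1`, and a zero-variance t test with equal means reports
`t = 0, p = 1` with a note.

## Synthetic data: what it emulates, and what it does not

Every generator is a pure function of its parameters and a seed.

**Hypnograms** come from an alternating-state semi-Markov model:
exponential bout durations with phase-specific means (rounded up to
whole epochs, minimum one), next states from a phase-specific
embedded chain with zero diagonal. Exponential durations are the
simplest memoryless stand-in; the closed-form stationary occupancy
(embedded-chain solution weighted by
`1/(1 - exp(-epoch_s/mu))` expected epochs per bout) is exported as
`stationary_occupancy()` and recovered by simulation in the tests.
The drug acts as a single multiplicative factor (`rem_effect`) on
transition probabilities into REM during the light phase only,
renormalized per row — mirroring a phase-specific REM-promoting
effect while leaving dark-phase dynamics untouched.

Default parameters were calibrated once, as follows. Stationary
occupancies anchor realism: about 47/44/9% wake/NREM/REM in the light
phase and 67/30/4% in the dark, REM entered almost exclusively from
NREM and scarcer in the active phase. Bout means (light W/N/R =
1.25/1.15/0.5 min, dark 2.15/0.95/0.4 min) are on the short, frequent
end of reported rodent ultradian cycling; they were chosen so that a
plausible phase-specific effect (`rem_effect = 1.6`, roughly +18
light-phase REM minutes) is detectable by the mixed ANOVA interaction
with 10 animals per group in at least 80% of replicates, the
detectability target the default effect size is defined by. The same
target fixes the power-analysis problem sizes used throughout:
two groups of 10 simulated animals, 24 h per animal, 200 Monte-Carlo
replicates per arm.

**Signals** are per-epoch spectrally shaped Gaussian noise: the EEG
target spectrum equals the state's weight inside each configured band,
its broadband weight elsewhere below 25 Hz, plus a 1/f floor; the EMG
is white noise at the state's RMS with the strict ordering
REM < NREM < WAKE. Epochs are stationary and statistically — not
sample-wise — continuous at boundaries. This is *not* biophysical
EEG: there are no spindles, no artifacts, no arousals, no
state-transition dynamics, and no volume-conduction structure.
Passing recovery tests on these signals demonstrates that the scoring
rules invert the generative assumptions; it does not certify scoring
accuracy on real recordings, which is why the scoring module keeps
every threshold exposed.

**Spike trains** superpose a tonic Poisson process and an independent
Poisson process of burst events, each replaced by 2–4 spikes whose
ISIs are drawn inside the detection thresholds; both rates are scaled
by the block's ground-truth multiplier, and the merged train enforces
a 1 ms refractory floor. Injecting bursts as compound events (rather
than a doubly stochastic rate) is what makes exact ground-truth burst
labels available. Spike waveforms, noxious-stimulus responses and
anesthesia-state dynamics are out of scope — times only.

**PK curves** follow the one-compartment absorption solution
`C(t) = S ka/(ka-ke) (e^{-ke t} - e^{-ka t})` with optional lognormal
noise; **Ct tables** place the control target at reference Ct plus a
baseline offset and shift the test group by the ground-truth ddCt.

## Numerical choices and degenerate inputs

* EDF is the signal interchange format (open standard, 16-bit): the
  writer auto-scales a symmetric physical range per channel, bounding
  round-trip error by range/2^16 per sample; it requires integer Hz
  and whole-second records. Non-finite samples are rejected at write
  time.
* Readers validate eagerly and name the offending row or field;
  downstream code assumes clean inputs.
* All-zero EEG is "unscorable" (error), a zero-power epoch is a
  "degenerate epoch" (error), a silent baseline block cannot be
  normalized (error), and an SFI window without sleep is undefined
  (error).
* The terminal fit refuses non-positive concentrations and
  non-negative slopes ("no elimination phase").
* Ties and boundaries: half-open everywhere (bands, blocks, phases),
  strict `< 80 ms` / inclusive `<= 160 ms` for bursts, spike exactly
  at a block boundary counts in the next block.

## Known limitations

Scoring is a transparent stand-in for expert scoring, not a
replication of it; real-data accuracy is untested by construction.
Band edges are conventions, not recovered quantities. The mixed ANOVA
does not implement sphericity corrections for within factors with
more than two levels, and the NCA deliberately omits compartmental
fitting, bioavailability and clearance (not derivable from
concentration data alone). The semi-Markov generator has no ultradian
or circadian structure beyond the two-phase parameter switch.
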