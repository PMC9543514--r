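---
title: "Methods: place-field remapping analysis and its synthetic testbed"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: place-field remapping analysis and its synthetic testbed}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`placeremap` analyses open-field place-cell recordings across a
light/dark/light (L1/D/L2) session sequence: rate maps, place-field centres
of mass, remapping geometry, unit classification, and LFP band power. This
vignette documents the models, the tunable parameters and their defaults,
the numerical choices, and what the synthetic-data generator does and does
not emulate.

## Rate maps

The arena (default 80 × 80 cm, the square arena of the experimental design
this package targets) is divided into square bins with the origin at the
south-west corner, half-open intervals and bin centres at
`(i + 0.5) · bin_size`. The default `bin_size` of 2.5 cm gives a 32 × 32
grid; recording systems in this class rarely resolve position much below
this scale. Occupancy assigns each position sample half of each adjacent
inter-sample interval; spikes are assigned to the bin of the temporally
nearest position sample. Bins occupied for less than `min_occupancy`
(default 0.1 s) are masked invalid and excluded from every downstream
statistic. No speed filtering of spikes is applied.

**Smoothing.** The smoothed map is an occupancy-weighted boxcar: spike
counts and occupancy are each summed over a `smooth_bins × smooth_bins`
window (default 5 × 5) restricted to valid bins, and then divided. We chose
this over smoothing the raw rate map directly for a numerical reason: at
the sub-hertz firing rates typical of claustral place cells (~0.35 Hz,
roughly 200 spikes in a 10-minute session spread over ~1000 bins), a bin
visited for 0.1–0.2 s that happens to contain one spike has a raw rate of
5–10 Hz, and averaging raw rates propagates such outliers into spurious
peaks. Dividing smoothed counts by smoothed occupancy weights each visit by
its duration, which stabilises exactly these bins. With the 5 × 5 window the
smoothed-map argmax lands within two bins of a simulated field centre
(median over seeds), and the plug-in information estimate of a spatially
uniform cell stays well below the 0.5 bits/spike classification threshold;
a 3 × 3 window of raw rates satisfies neither at these firing rates. Both
the kernel size and smoothing itself are configurable.

## Place fields and centres of mass

A place field is the largest 4-connected component of valid bins whose
smoothed rate reaches `peak_fraction` (default 0.2) of the global peak,
provided it spans at least `min_bins` bins (default 9, i.e. ~56 cm² —
roughly the smallest region one would call a field at this bin size). Ties
on component size are broken by higher mean rate, then lowest linear bin
index, so detection is deterministic. The field's centre of mass (COM) is
the rate-weighted mean of its member-bin centres, using the smoothed rate
and the field's bins only — the COM of *the field*, not of the whole map.

## Remapping geometry

For each unit with a field in all three sessions, the package reports the
pairwise COM distances and the L1DL2 angle: the angle at the dark-session
COM between the vectors to the two light-session COMs
(`arccos` of their normalised dot product, cosine clamped to [−1, 1] to
absorb floating error in collinear configurations). When the dark COM
coincides with a light COM the angle is undefined; such units are reported
as `no_remap` rather than given an arbitrary angle. Units lacking a field
in any session are excluded from the aggregates and listed with a reason.
Aggregates are mean ± SEM (sd/√n), with the SEM absent for n = 1. Within a
report, the remapping cohort is further restricted to units classified as
place cells in at least one session, so spatially uniform bursting units
cannot dilute the angle statistics.

## Unit metrics and classification

Skaggs spatial information
`I = Σᵢ pᵢ (λᵢ/λ̄) log₂(λᵢ/λ̄)` is computed over valid bins on the smoothed
map (the raw-map plug-in estimator is strongly upward-biased at low spike
counts), in bits per spike; zero-rate bins contribute zero. Spatial
coherence is the Pearson correlation between the raw rate map and the mean
of each bin's valid 3 × 3 neighbours (centre excluded); it deliberately uses
the raw map, since its purpose is to measure local regularity of the
unsmoothed firing. Waveform amplitude is the difference between the first
positive and first negative peak of the mean waveform; width is taken at
25% of that amplitude around the principal peak, with linear interpolation
between samples. Bursts are maximal runs of ≥ 2 spikes with consecutive
ISIs ≤ 6 ms; candidate bursts separated by less than a 50 ms inter-burst
interval merge into one event. We read the discrimination bound "ISI of
6 ms" as an upper bound on within-burst ISIs, the standard convention for
burst detection.

Classification: a unit is a **place cell** if information ≥ 0.5 bits/spike,
coherence ≥ 0.25, mean rate ≥ 0.25 Hz, and a field was detected. Units
failing that are **bursting cells** when burst propensity ≥ 0.1 and mean
rate ≥ 1 Hz — an operationalisation of the fast, heavily bursting,
non-spatial profile of such units (the 3 Hz / near-total burst propensity
regime); both bounds are configurable. Everything else is unclassified.
ISI-histogram autocorrelation scoring is not part of the classification.

## LFP band power

Power spectral densities use Welch's method: 2 s segments, 50% overlap,
per-segment linear detrending, Hamming window, one-sided density scaling
(the PSD integrates to the signal variance). The 2 s window gives 0.5 Hz
resolution — five grid points across the narrow delta band — while still
averaging ~600 segments in a 10-minute trace; window and overlap are
configurable.

Band power integrates the PSD with a composite Simpson rule *anchored to
the frequency grid*: each pair of grid intervals contributes the integral
of its quadratic interpolant over its overlap with the band. Anchoring
matters: re-starting the Simpson pairing at every band edge weights a given
frequency bin differently in a narrow band than in the 1.5–90 Hz total, so
a pure tone's relative power could fall far below 1 even though all its
energy lies in one band. With grid anchoring, band integrals are exactly
additive over sub-bands, exact for quadratic spectra, and weight every bin
consistently. Bands default to delta 1.5–4 Hz, theta 5–11 Hz and gamma
30–90 Hz, with total power over 1.5–90 Hz; the 4–5 and 11–30 Hz gaps are
deliberately unassigned, so relative powers sum to less than 1.

## Paired statistics

Session contrasts (L1 vs D, D vs L2, L1 vs L2) use two-tailed paired tests
over units (or LFP channels): a paired t test when a Shapiro–Wilk check on
the differences does not reject normality at α = 0.05, a Wilcoxon
signed-rank test otherwise; the gate can be overridden. Degenerate inputs
are flagged, not silently tested: all-zero differences report t = 0, p = 1;
constant non-zero differences have no valid t statistic; the signed-rank
test errors when every difference is zero. No multiple-comparison
correction is applied — contrasts are reported unadjusted, and readers
should treat the p-values accordingly.

## The synthetic-data generator

The generator emulates the L1/D/L2 experiment: three 10-minute sessions in
an 80 × 80 cm arena with 50 Hz position tracking.

- **Trajectory**: two-dimensional Ornstein–Uhlenbeck velocity (correlation
  time 1 s) with stationary Rayleigh speed matching the 10 cm/s mean
  running speed of a foraging rat; the integrated path is folded into the
  arena, which is equivalent to specular wall reflection and preserves
  speed. The paths are diffusive and cover the arena unevenly within a
  session, as real foraging does.
- **Place cells**: inhomogeneous Poisson spiking by thinning, with
  intensity `baseline + (peak − baseline)·exp(−d²/2σ²)`. Defaults
  (peak 3 Hz, σ = 10 cm, baseline 0.05 Hz) put the session mean rate near
  0.35 Hz in light; the field width is an assumption — field sizes are not
  something we could calibrate against a reported value — chosen so a field
  occupies a few percent of the arena. The dark session scales the
  intensity by 0.65 (≈ 0.23/0.35, the reported light-to-dark rate drop) and
  the second light session by 1.1.
- **Remapping geometry**: each cell's light COM is drawn uniformly at least
  `margin` (16 cm) from the walls; the dark COM is displaced by the
  configured shift (default 12.75 cm) in a random feasible direction, and
  the L2 COM is the L1 COM *rotated about the dark COM* by the configured
  angle (default 50°). This makes the true angle exactly the configured
  one with both legs equal to the shift; a 0° angle returns the field to
  its light position, i.e. perfectly stable light fields. A 180° angle
  gives the collinear configuration with the dark field between the two
  light fields.
- **Bursting cells**: burst events from a renewal process (minimum
  inter-burst gap 150 ms plus an exponential tail, event rate set so the
  overall rate is 3 Hz), each carrying 2 + Poisson spikes (mean 4) at
  1.5–3 ms within-burst intervals.
- **LFP**: spectrally shaped Gaussian noise at 250 Hz (Nyquist comfortably
  above the gamma edge). The expected spectrum is flat within each target
  band at the height giving its requested relative power; the residual
  power is spread over the spectral gaps in proportion to ∫1/f (LFP
  spectra fall roughly as 1/f), plus a small white floor. Shaped noise
  rather than sinusoids gives Welch estimates realistic variance. Light
  sessions default to relative powers (δ, θ, γ) = (0.312, 0.274, 0.099)
  with ~5235 µV² total; dark sessions to (0.280, 0.314, 0.099) with
  ~4972 µV², reproducing the reported dark shift toward theta.
- **Waveforms**: a biphasic template (dominant trough, smaller
  after-potential) per unit, with log-normal amplitude (~135 µV) and width
  (~250 µs) variation, sampled at 48 kHz.

Everything is a pure function of its arguments and a seed; the on-disk
format stores ground truth in a `manifest.json` so parameter-recovery tests
can compare estimates to truth.

**What the generator does not emulate** — and hence what passing tests do
not show about real data: electrode drift and cluster-cutting errors (units
never disappear mid-experiment, though the analysis handles missing
fields), theta-modulated or speed-modulated firing, head-direction or
boundary coding, non-Poisson spike-history structure in place cells,
line noise and movement artefacts in the LFP, and any pharmacology. Tests
establish that the estimators recover known ground truth under clean
conditions, not that the biological effects are real.

## Problem sizes and numerical conventions

Simulation-based tests use 10-minute sessions at 50 Hz tracking —
the experiment's own session length — with cohorts of 6–20 cells and up to
20 replicate seeds for remapping recovery, and a 49-unit (40 place + 9
bursting) cohort spread over 13 simulated animals for classification;
spectral recovery uses 600 s traces. These sizes put the Monte-Carlo error
of each recovered quantity well inside the tolerance it is tested at. All
randomness is derived from explicit seeds; RNG state is saved and restored
around every simulator call, so generation is reproducible and
order-independent. Ties in field detection are broken deterministically;
the arccos argument is clamped to [−1, 1]; undefined quantities (zero mean
rate, zero variance, coincident COMs) raise typed errors or flagged rows
rather than silently returning 0.

## Known limitations

- The COM distance estimator is noise-inflated: with estimation error σ on
  each COM, distances are biased upward by O(σ²/d); at 600 s sessions the
  bias is a few percent of a 12.75 cm shift. Angles are unbiased at
  intermediate angles but compress toward the interior near 0° and 180°.
- Rate-map information and coherence retain positive small-sample bias
  even on the smoothed map; classification thresholds should be applied to
  sessions of comparable duration, as in the original design.
- Welch's method with 2 s windows slightly underestimates the narrow delta
  band next to the strong low-frequency roll-off (leakage and detrending);
  recovered relative delta runs ~0.02 below target, within the tolerances
  used here.
- The paired tests assume exchangeable units; units recorded on both days
  are treated as independent triplets per day.
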