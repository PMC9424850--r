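---
title: "Methods: fatigue, stability and end-point accuracy for repetitive tapping"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: fatigue, stability and end-point accuracy for repetitive tapping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette documents the models and the numerical choices behind
`tapfatigue`, in the spirit of a methods section: what each stage assumes,
which knobs matter, what the synthetic generator does and does not
emulate, and where the design was genuinely open.

## The task and its protocol constants

One *cycle* is tapping four touch screens TS1→TS2→TS3→TS4
counterclockwise and returning to TS1; a session is 400 cycles at one
worktable height (LOW: elbow height; HIGH: 120% of it), split into 10
*bins* of 40 cycles, later pooled into 5 *periods* of 2 bins. The four
inter-target intervals are *stages* ST1–ST4. Each screen is 320×240 px at
0.153 mm/px and displays a 110 px (16.83 mm) target circle. Elsewhere a
displayed diameter twice that figure is quoted for the same apparatus;
the two differ by exactly a factor of two, so one of them is a radius.
`circle_spec()` follows the pixel figure (110 px diameter), and both the
diameter and the pitch are configurable.

## EMG chain

Assumptions: surface EMG is a locally stationary stochastic process within
a 0.125 s window; amplitude (windowed RMS, as % of an MVC reference) is
the activity measure and the median of the windowed power spectrum (MF)
is the fatigue measure, declining as the spectrum compresses toward low
frequencies.

Numerical choices, all pinned in `pipeline_config()`:

* **Window geometry.** 0.125 s windows at 50% overlap. The window length
  in samples is rounded to an *even* count (`2*round(window*fs/2)`, 240
  samples at 1926 Hz) so that the 50% stride is exact and one window is
  exactly two strides; the nominal duration error is 0.3%.
* **Band-pass.** 4th-order Butterworth high-pass (10 Hz) and low-pass
  (950 Hz) stages, each applied forward–backward (zero phase) via
  `signal::filtfilt`. The cascade is numerically safer than a single
  band-pass design with an upper edge at 0.987 of Nyquist.
* **MF estimator.** One Hamming-tapered periodogram per window —
  deterministic and matching the per-window MF definition — with the
  median interpolated linearly within the crossing bin. Cumulative power
  is attributed to bin *upper edges*: the bin-centre convention biases MF
  by half a bin (−4 Hz at the 8 Hz resolution of a 240-sample window),
  which simulation on flat-band noise exposes immediately. All-zero
  windows return `NA`, never 0.
* **Per-bin MF** is the mean of window MFs falling in the bin (windows
  assigned by centre time to cycles, cycles to bins). Pooling windows
  into one long spectrum per bin was the alternative; mean-of-windows was
  chosen because the single-window median is unbiased but noisy (~20%
  SD on a flat band), and averaging ~700 windows per bin brings the bin
  error to the percent level, which the recovery tests measure.
* **MVC reference.** The per-channel reference is the *maximum* of the
  moving RMS over the MVC trial — the conventional reduction when the
  trial is a sustained maximal effort.
* **CCI.** Trapezoidal integrals of min and sum of the two %MVC series
  over each stage interval and the full cycle, on the window-centre grid;
  an interval holding fewer than two window centres, or a vanishing
  denominator, yields `NA` with a warning. The anterior deltoid is labelled
  agonist and the posterior antagonist; the min() makes the index
  symmetric in that assignment.

## Kinematics and variability

Cycles are cut at TS1 taps and linearly interpolated onto 100 equally
spaced points including both boundaries (`time_normalize`); degenerate or
irregular cycles are excluded and logged. KV uses the sample (n−1) SD
across a bin's cycles at each phase point, averaged over phase, with the
per-sensor value the Euclidean norm over its three axes. Per-stage KV
resamples each stage to 25 points (a quarter of the cycle's 100) so
stage values are comparable across stages of different duration; whether
the original analysis resampled stages or used raw-duration slices is not
stated, and this choice is exposed via `stage_points`.

## Local dynamic stability

The state space is the first three principal-component score series of
the nine centred acceleration channels — no additional delay embedding by
default (a `delay_embedding` option exists), because the multichannel PCA
construction already spans the movement. PCA is fitted per
participant-session (per height), matching per-case reporting. Because
time normalisation includes both cycle boundaries, the last sample of one
cycle duplicates the first of the next; `build_state_space` drops the
duplicate so that one state-space step advances the phase everywhere.
Neglecting this seems harmless but measurably corrupts the divergence
curve: boundary samples otherwise pair with their duplicates at zero
distance and jump apart one step later.

Divergence follows the Rosenstein construction: for every sample the
nearest Euclidean neighbour at temporal separation ≥ one cycle (Theiler
window, 100 samples) is found by exact scan (`src/neighbors.cpp`;
verified against a brute-force R oracle), and `y(k)` is the mean log
distance after `k` steps, `k = 0..50`, with pairs running past the record
end excluded and zero-distance duplicates dropped from the log mean.
λ is the least-squares slope of `y(k)` over `[0, h]` for horizons
`h = 5, 10, 25, 50` samples (5%, 10%, quarter, half cycle). The fit
starts at `k = 0` by default (`lle_fit_start` exposes a transient skip,
used e.g. for chaotic-flow fixtures whose early curve overshoots);
λ is reported per normalised sample, so per-cycle rates are ~100×.
Per-bin λ restricts the query points to the bin while neighbours come
from the whole session.

## End-point performance

AS follows the ratio formula exactly and is deliberately not clamped:
taps outside the circle score negative. TD is the package's central
interpretive choice: the protocol names "tapping deviation" without
defining it, and `tapping_deviation()` implements it as the mean distance
of a bin's taps from *their own centroid* — a precision (repeatability)
measure deliberately distinct from AS's accuracy-to-target — with a
config switch (`td_reference = "center"`) to an RMS-about-centre variant
for sensitivity analyses.

## Statistics

Ratios: every index is divided by the participant's first LOW bin; MF by
the first bin of its own height (so MF height effects are about decline
rate, not baseline). The height comparison is a two-sided paired t-test
pooling participant × bin pairs (18 × 10 in the full design); pooling
bins as pairs matches the protocol's stated group sizes but treats
within-participant bins as independent pairs, which is anticonservative —
noted, not "fixed", because the package reproduces the published
procedure. Time effects: per height, subjects × 5 periods (period = mean
of its two bins) enter a one-way repeated-measures ANOVA computed from
the two-way subject × period decomposition (cross-checked in tests
against `aov` with an `Error(subject/period)` stratum), without
sphericity correction by default (a Greenhouse–Geisser option exists).
Follow-ups P2–P5 vs P1 are paired t-tests flagged at 0.05/4 = 0.0125 and
gated on the ANOVA. Under a simulated global null the two 0.05-level
tests sit at their nominal level while the gated family is conservative
(familywise error well below 0.05) — the expected behaviour of a gated
Bonferroni procedure, asserted as such in the tests.

## The synthetic generator

The generator's defaults are the study conditions: 400 cycles per height,
1926 Hz EMG, three muscles with linear MF declines (e.g. anterior
85→80 Hz at LOW, 85→72 Hz at HIGH), constant per-height %MVC levels
(higher at HIGH), isotropic bivariate-normal taps (σ 1.2 mm LOW, 1.6 mm
HIGH; isotropic normality is an assumption — no distributional
description of real tap errors exists), and linear cycle-duration trends
(1.10→1.00 s LOW, 1.05→0.95 s HIGH; faster at HIGH). The accelerometer
rate is not a protocol constant and defaults to 100 Hz.

* **EMG.** Gaussian white noise shaped per overlap-added Hann frame by a
  flat band `[10, 2·MF−10]`, whose midpoint is the target MF — the median
  of a flat spectrum is its band midpoint, so the planted MF is exact by
  construction (fractional-bin edge weights keep the effective band
  exact). The windowed RMS contract is then enforced *exactly* by
  normalising the energy of every half-window block: an analysis window
  is two blocks, so its RMS is the quadratic mean of two adjacent block
  targets. The MVC trial is a separate 5 s constant-amplitude recording.
* **Accelerations.** Nine channels are an orthonormal 9×3 mixing of a
  latent signal plus iid sensor noise. The latent signal is a
  non-self-intersecting 3-D cyclic template (a circle plus a weak second
  harmonic) plus a perturbation with a *planted divergence exponent*: a
  scalar expanding map `q → e^γ q mod 1`, iterated once per
  normalised-phase step along a fixed latent direction. Its largest
  Lyapunov exponent is exactly `γ = divergence_gamma` (the latent-pair
  oracle in the tests confirms this to machine precision), divergence
  persists across cycle boundaries, and the process stays bounded. A
  perturbation whose magnitude is periodic in the cycle (e.g. grown
  within a cycle and re-seeded at each boundary) cannot work here: if the
  pair log-distance depends only on phase, the phase-averaged divergence
  curve is constant, so no exponent is recoverable — this drove the
  design. For `γ < 0` a within-cycle contraction re-seeded per cycle is
  used instead. A scalar (not 3-D) perturbation keeps map-space pair
  separations far below the fold width so that fold events, which destroy
  diverging pairs, stay rare over the fitted horizons.
* **Alignment.** The λ- and KV-recovery configurations use 0.99 s cycles
  at 100 Hz so the 100 normalised phase points coincide with acceleration
  samples; with misaligned grids, linear interpolation attenuates white
  sensor noise by up to √(2/3) and smooths the planted map, which is a
  property of resampling, not an estimator defect. These validation
  configurations also set sensor noise to zero (λ) or the perturbation
  to zero (KV) so each planted quantity is identified on its own.

What the generator does *not* emulate: biomechanically realistic limb
dynamics or muscle synergies, motor-unit structure or mains hum in the
EMG, learning or fatigue-induced strategy switching, touchscreen
quantisation (pixel coordinates are continuous), and any coupling between
streams beyond the shared tap clock. Passing recovery tests therefore
shows the *estimators* are correct at realistic signal scales, not that
real sessions will look like the synthetic ones.

## Problem sizes and tolerances

Recovery checks run at the full protocol size (400 cycles; 60 MF bins;
400 taps per screen) where the closed-form targets hold to a few percent:
per-bin MF within ±5%, KV within 5% of σ (axis) and σ√3 (sensor), TD
within 5% of σ√(π/2), λ5 within 10% of γ. Unit fixtures use 2–150 cycles.
The statistical calibration uses 1000 null replicates of the 18-subject
design. The chaotic-flow cross-check integrates 25 000 RK4 steps of a
standard 3-D flow and compares the divergence-curve slope in its scaling
region against tangent-space (Benettin) propagation within 15%.

## Known limitations

* The pooled participant × bin pairing of the height t-test is
  anticonservative (see above); `cohort_stats()` reproduces it by design.
* Per-window MF is noisy by construction (single periodogram); only
  bin-level MF is validated.
* λH saturates on strongly diverging sessions (neighbour distances reach
  the perturbation's extent within half a cycle); λ5/λ10 are the reliable
  recovery targets, mirroring how short-horizon exponents are preferred
  in practice.
* The generator's fold events give λ a small (~+5%) upward bias at
  γ = 0.05; this is inherent to keeping an expanding process bounded and
  is inside the 10% recovery band.
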