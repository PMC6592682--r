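---
title: "Quantifying intracardiac flow by multigrid ensemble micro-PIV"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying intracardiac flow by multigrid ensemble micro-PIV}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cardiopiv)
```

## The measurement problem

Movies of circulating, fluorescently labeled red blood cells in the
embryonic zebrafish heart carry a full description of intracardiac
hemodynamics, but extracting it is hard for two reasons.  First, tracer
seeding in any single frame pair is sparse and noisy, so classical
two-frame particle image velocimetry (PIV) is unreliable.  Second, the
flow is pulsatile: velocities at two different cardiac phases must never
be mixed.  `cardiopiv` addresses both with *ensemble* PIV over
*phase-aligned* frame pairs: a long recording (hundreds of frames,
roughly 17 heartbeats) is first aligned to the cardiac cycle, and the
correlation evidence from every pair that samples the *same phase* is
averaged before a velocity is read off.

The downstream summaries are the ones used to compare healthy and
injured hearts: cross-sectional flow rates
$Q = \int_a^b \vec v \cdot \vec n \, dl$, phase-resolved flow profiles
$Q(t)$ over one cycle, and the **Fundamental Harmonic Index**
$\mathrm{FHI} = Q_1 / Q_0$, the amplitude of the fundamental flow
harmonic relative to time-averaged flow.  A forward, valve-gated flow has
FHI below 1; a reversing, oscillatory flow (as after ventricular injury,
when retrograde ventricle-to-atrium flow appears) has FHI above 1.

## Cardiac phase alignment

The period is estimated from the movie itself: every pair of frames a lag
$L$ apart is compared by whole-image Pearson correlation, the mean
similarity per lag is scanned for peaks, and the first credible peak is
refined in two steps — parabolic interpolation around the integer lag,
then re-reading the peak near the highest available *multiple* of the
period, which divides the interpolation error by the harmonic order.
Frames are block-averaged to at most 64 px per side first; the period is
a whole-image property and survives heavy downsampling.

A peak must exceed the baseline (median similarity) by 0.2 to count;
otherwise the stack is declared aperiodic — this catches constant movies,
pure noise, and arrhythmic recordings.  One global period is fitted per
movie; per-cycle re-alignment is not attempted.  Phase bins default to
`round(period)` bins, i.e. one bin per frame of the cycle, which gives
maximal pooling with exactly one frame pair per bin per cycle.

## Ensemble correlation and the multigrid schedule

Each interrogation window is compared by zero-mean normalized (Pearson)
cross-correlation over all integer lags within the search radius.
Normalized planes are bounded in $[-1, 1]$, which makes averaging across
pairs with different brightness meaningful; the ensemble plane for a
phase bin is the arithmetic mean over all its pairs, and only then is the
peak located.  Two backends exist — compiled direct summation and an
FFT/integral-image path — and are tested to agree to $10^{-8}$.

Resolution is built up over three passes: 48 × 48 px windows at 24 px
spacing, then 32 × 32 at 12 px, then 16 × 16 at 4 px.  With the default
calibration of 1.75 µm/px the final vector spacing is exactly 7 µm.  Each
pass bilinearly interpolates the previous field to the new centers,
rounds it to an integer predictor shift (window-offset PIV), and
correlates only the residual; subpixel precision enters once, through a
three-point Gaussian fit at the final peak (falling back to a parabolic
fit when a neighbor is non-positive, and skipping refinement entirely
when the peak correlation is exactly 1, which identifies an exactly
integer shift).  The first pass searches ±12 px — generous for the ~6 px
frame-to-frame displacements typical at these frame rates — and later
passes ±4 px around the predictor.

Vectors are screened twice: an ensemble-peak-correlation floor (default
0.1) rejects windows whose pooled planes carry no coherent signal, and
the normalized-median test over the 8-neighborhood (threshold 2, noise
floor 0.1 px) rejects isolated outliers, which are replaced by the median
of their valid neighbors and tagged as interpolated rather than measured.

## Flow rates, profiles, and the FHI

A cross-section is a user-drawn line from $a$ to $b$ with unit normal
$\vec n$ (90° counter-clockwise from the line in image coordinates, so a
section drawn top-to-bottom across a left-to-right channel counts
rightward flow as positive).  The integral is discretized with the
rectangle rule at spacing `dl`, conventionally 4 px (7 µm).  Sample
positions are *midpoints* $s = dl/2, 3dl/2, \dots$: with midpoint
sampling the quadrature and the included length $n \cdot dl$ are exactly
consistent, so a uniform flow returns exactly its normal velocity and a
parabolic (Poiseuille) profile returns $\tfrac23 v_{max}$ to within
0.02 % at 50 samples.  Endpoint sampling, by contrast, over-counts the
line length by one sample and biases the normalized flow by ~2 %.

Both the raw line integral (µm²/s in 2-D) and the length-normalized mean
normal velocity (µm/s) are reported; the normalized value is the headline
number, matching how flow rate is conventionally plotted in velocity
units.  FHI is identical under either choice.  Profiles average three to
five sections per region (and multiple z-stacks when available, with
equal weight); a section failing on more than 25 % of phase bins is
dropped with a warning.

From the DFT $c_m = \tfrac1N \sum_k Q_k e^{-2\pi i k m/N}$ of the
phase-ordered profile, $Q_0 = \mathrm{Re}(c_0)$, $Q_1 = 2\lvert c_1
\rvert$ (so a pure cosine of amplitude $A$ gives $Q_1 = A$), and
$\mathrm{FHI} = Q_1/\lvert Q_0\rvert$.  The absolute value keeps FHI a
magnitude even for net-retrograde profiles; near-zero mean flow
($\lvert Q_0\rvert < 10^{-9}\max\lvert Q\rvert$) is an error rather than
an unstable ratio.  Non-uniformly sampled profiles (e.g. with a dropped
bin) are linearly resampled onto a uniform phase grid first; FHI is
invariant under positive scaling and cyclic phase shifts, and the tests
hold it to $10^{-9}$.

## The synthetic recordings

No public recordings accompany this kind of experiment, so validation
rests on a generator whose defaults mirror the acquisition the pipeline
targets: 512 × 128 px frames at 1.75 µm/px, 75 frames per second (within
the 50–100 fps acquisition range; 40/3 ms per frame), 500 frames, and a
0.4 s cardiac period — 30 frames per cycle, about 17 cycles per movie.
Tracers are rigid, inertia-free point particles rendered as
pixel-integrated Gaussian spots (FWHM 5.25 µm ≈ 3 px, so the correlation
peak is well sampled and peak-locking is negligible) on a constant
background with additive Gaussian sensor noise.  Flow fields are
separable channel flows $u(y, t) = s(y) f(t)$ in a straight lumen whose
walls are the y-bounds — a deliberate idealization of a chamber
cross-section.

Two temporal regimes define the study conditions.  The *control* regime
is a single-harmonic waveform with amplitude half the mean
($f(t) = 400 + 200\cos$, µm/s; analytic FHI 0.5, never reversing).  The
*ablated* regime has amplitude three times the mean ($f(t) = 250 +
750\cos$; analytic FHI 3.0, reversing for ~39 % of the cycle) — the
oscillatory, retrograde-flow state of the injured heart.  The default
seeding density, 0.01 particles/µm² (~8 per final 16 × 16 px window), is
unstated in any protocol; it was chosen once as the regime where
single-pair PIV is serviceable but ensemble averaging visibly helps, and
the sparse-seeding tests drop it to 0.0015 to make single-pair PIV fail
outright.

Periodicity is exact by construction: particle trajectories are evaluated
at the frame time modulo the period, so noise-free frames an integer
period apart are bit-identical, which is what the alignment stage needs
to see.  The cost is that the one consecutive pair per cycle that crosses
the wrap is non-physical; the peak-correlation floor flags its vectors
and the profile stage drops the affected bin, after which the FHI is
unaffected (it is phase-shift invariant and tolerant of one resampled
bin).  With `periodic_tiling = FALSE` the generator instead advects
particles continuously with inflow recycling — configurations are then
*not* periodic, whole-image alignment has no peak to find, but every
cycle samples the same flow state with fresh tracers.  That is the regime
ensemble correlation exists for, and the one used to demonstrate it.

What the generator does **not** emulate: moving chamber walls, 3-D and
out-of-plane motion, optical PSFs beyond a Gaussian, Poisson shot noise,
cell–cell interactions, and deformable geometry.  Passing tests therefore
demonstrate the correctness of the estimators under the stated model, not
robustness to every property of live recordings.

## Problem sizes used in the tests

The shipped tests scale the acquisition down so the whole suite runs in a
few minutes while keeping every ratio that matters (frames per cycle,
particles per window, displacement per frame in px): end-to-end FHI
recovery uses 96 × 256 px × 300 frames (10 cycles) at five seeds per
regime, recovering the analytic FHI within a few percent in both regimes
(the acceptance margin is 15 %) with the ablated > control ordering in
every replicate; alignment and ensemble benchmarks use 500–510-frame
movies at 64–96 px height; the shear benchmark uses the full
48/24 → 16/4 px schedule on 128 × 256 px frames with a 6 px maximum
displacement.  Reported quantities in the test suite and acceptance
script are always computed at run time from these generated movies.

## Numerical choices and edge cases

* Pixels are 0-based with centers at integer coordinates; x is the
  column, y the row (positive down); displacements are measured in this
  frame, and `px/frame` converts to µm/s exactly as
  `px * pixel_size / (frame_interval/1000)` with no hidden rounding.
* Zero-variance windows produce a degenerate all-zero plane rather than
  `NaN`s; peaks on the search border are flagged and not refined.
* Exact peak ties resolve toward the smaller displacement magnitude,
  then lexicographically.
* ROI pixel membership uses the even-odd rule on pixel centers;
  background ROIs are pooled pixelwise before their mean is taken (the
  alternative — a mean of per-ROI means — differs only when background
  ROIs have unequal areas, and no rule is conventional).
* All randomness flows from explicit integer seeds; identical seeds give
  bit-identical movies, and identical pipeline configurations give
  byte-identical CSV outputs with verifiable manifest checksums.

## Known limitations

A single global period cannot follow beat-to-beat variability; strongly
arrhythmic recordings will (correctly) be rejected as aperiodic.  The 2-D
flow-rate integral is a per-plane quantity, not a volumetric rate; z
planes are analyzed independently.  FHI is undefined for zero-mean
profiles by construction, and near-zero-mean profiles amplify noise in
the ratio — compare regimes through both $Q_0$, $Q_1$ and FHI when mean
flow is small.  The normalized-median validation can flag legitimate
vectors at the outer rows of very coarse first-pass grids under strong
shear; such vectors are replaced by neighbor medians and refined away by
later passes.
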