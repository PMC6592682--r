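# cardiopiv

Quantifying intracardiac hemodynamics from beating-heart time-lapse
movies: multigrid **ensemble micro-PIV** with cardiac-cycle phase
alignment, cross-sectional **flow rates**, and the **Fundamental Harmonic
Index** (FHI) that separates forward from oscillatory flow — plus the
standard ROI quantitation formulas used alongside such recordings.

## Who this is for

Labs imaging circulating labeled red blood cells (or any tracer) in small
beating hearts — e.g. confocal movies of the embryonic zebrafish heart at
50–100 fps — who need velocity maps and flow summaries from recordings in
which any *single* frame pair is too sparse and noisy for classical PIV.

## The method in brief

1. **Phase alignment.** The cardiac period (in frames, real-valued) is
   estimated by maximizing whole-image temporal cross-correlation over
   frame lags, refined to sub-frame precision; every frame gets a phase
   in [0, 1) and a phase bin.
2. **Ensemble correlation.** For each interrogation window and phase
   bin, the zero-mean normalized cross-correlation planes of *all*
   same-phase frame pairs across the ~17 recorded cycles are averaged
   before peak detection — this is what rescues sparse seeding.
3. **Multigrid refinement.** Passes at 48×48/24 px → 32×32/12 px →
   16×16/4 px windows, each re-centering windows with the previous
   pass's field; at 1.75 µm/px the final vector spacing is 7 µm.
   Vectors are validated by a peak-correlation floor and the
   normalized-median outlier test.
4. **Flow summaries.** Flow rate across user-drawn sections,
   Q = ∫ᵃᵇ v⃗·n⃗ dl (dl = 4 px), averaged over 3–5 sections per region;
   phase-resolved profiles Q(t) over one cycle; and
   FHI = Q₁/Q₀ from the profile's Fourier coefficients
   (Q₀ = mean flow, Q₁ = fundamental-harmonic amplitude).
   FHI < 1: forward pulsatile flow.  FHI > 1: reversing, oscillatory
   flow, the signature of the injured ventricle.
5. **ROI quantitation.** Fractional area change
   FAC = (EDA − ESA)/EDA × 100, background-corrected area-normalized
   fluorescence with fold change, labeled-area coverage, and normalized
   ventricular area.

A synthetic movie generator (`generate_sequence()`) with analytic ground
truth stands in for recordings, so the whole chain is testable end to
end.

## Worked example

Simulate a control-like (forward pulsatile) and an ablated-like
(oscillatory, partly retrograde) recording and recover their FHI:

```r
library(cardiopiv)

run <- function(regime, out) run_pipeline(list(
  out = out, seed = 1,
  simulate = list(flow = regime, n_frames = 300,
                  image_shape = c(96, 192), density = 0.012)))

mc <- run("control", tempfile())
ma <- run("ablated", tempfile())
cat(sprintf("period %.2f frames | FHI control %.3f | FHI ablated %.3f\n",
            mc$period_frames, mc$fhi, ma$fhi))
#> period 30.00 frames | FHI control 0.533 | FHI ablated 2.943
```

The control waveform is built with fundamental amplitude half the mean
(analytic FHI 0.5) and the ablated waveform with amplitude three times
the mean (analytic FHI 3.0, flow reversing ~39 % of each cycle); the
pipeline recovers both from the rendered movies to within a few percent,
and the ablated FHI exceeds the control FHI in every seeded replicate.
Each run writes `fields.csv` (per-phase vector maps), `profile.csv`
(Q(t) over one cycle), `fhi.csv`, and a `manifest.json` whose checksums
make the run verifiable (`verify_manifest()`).

Lower-level entry points: `align_cycles()`, `multigrid_piv()`,
`cross_section()` / `flow_profile()` / `fundamental_harmonic_index()`,
and `fractional_area_change()` & friends for ROI work.

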