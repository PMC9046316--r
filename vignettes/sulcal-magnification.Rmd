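---
title: "Methods: sulcal anatomy and the retinotopic magnification of V1"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sulcal anatomy and the retinotopic magnification of V1}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The question and the pipeline

Primary visual cortex (V1) maps the visual field continuously: eccentricity
(distance from fixation, in degrees of visual angle) increases along the
length of V1, and polar angle varies across it, with the V1/V2 border lying
at the vertical-meridian representations. Two occipital folds — the
retrocalcarine sulcus (rCaS), the vertical posterior termination of the
calcarine, and the external calcarine sulcus (eCaS) on the lateral surface —
occupy characteristic positions in this map that differ between humans and
macaques. `sulcmap` quantifies that relationship on triangle meshes of a
cortical hemisphere carrying per-vertex retinotopic measurements:

1. **Delineate V1** from polar-angle reversals: vertices near the upper and
   lower vertical meridians (±90°) form the two borders, thinned to
   edge-graph paths from their foveal to their peripheral ends.
2. **Construct the foveal confluence line**, a low-eccentricity path linking
   the two borders' foveal endpoints, and compute every vertex's geodesic
   distance `d` from it along the (pial) surface.
3. **Fit the cortical magnification function** `E = a (exp(b d) - 1)` by
   nonlinear least squares on all valid V1 vertices, and build a 2D
   histogram of eccentricity (0.5° bins) by cortical distance (1 mm bins)
   with per-sulcus isocontours at 99/75/50/25 % of each sulcus' maximum bin.
4. **Summarize each sulcus**: pial/white surface areas, percent of V1's
   pial area, mean eccentricity and eccentricity/distance ranges, and
   visual-field coverage (`x = E cos θ`, `y = E sin θ`).
5. **Compare species** with two-way fixed-effects ANOVAs
   (species × hemisphere), hemispheres entering as independent
   observations.

Because the human data this kind of analysis is usually run on are
restricted-access, the package ships a synthetic folded-V1 generator with
human and macaque presets; every stage is validated end-to-end against its
ground truth.

## The magnification model

`E = a (exp(b d) - 1)` maps cortical distance from the foveal confluence
(mm) to eccentricity (deg). The `- 1` forces `E(0) = 0`, which lets the
model fit foveal (< 1°) measurements; `a` (deg) scales the map and `b`
(1/mm) sets how fast eccentricity accelerates peripherally. The inverse is
`d(E) = log(E/a + 1) / b`, which the generator uses to place folds at
prescribed eccentricity bands.

The fit minimizes the sum of squared eccentricity errors with bounded
Levenberg–Marquardt (`minpack.lm::nlsLM`), start `(a, b) = (1.0, 0.05)`,
bounds `a ∈ (1e-6, 50]`, `b ∈ (1e-6, 1]`. The model has a shallow ridge —
for small `b d`, `E ≈ a b d`, so only the product `a b` is identified — and
a single start can stall on a near-linear solution when noise is high.
`fit_cmf()` therefore also tries a small fixed set of auxiliary starts and
keeps the lowest-SSE solution; the procedure stays deterministic given the
samples. `r_squared` is `1 - SSE/SST` on the fitted sample set, reported per
hemisphere.

## The synthetic generator

`generate_v1_patch()` builds an annular-wedge sheet: eccentricity runs
radially, polar angle angularly (±90° across the wedge), and the foveal
confluence is the short inner arc (radius 2 mm). Folds are raised-cosine
corrugations expressed through the tangent angle of unit-speed profile
curves, so the radial coordinate is arc length along the folded surface.
The generator coordinate `d` of each vertex is then *measured* as the
cumulative radial arc length of its angular column on the embedded mesh,
and ground-truth eccentricity is `a (exp(b d) - 1)` of that measured `d` —
truth and geometry are exactly self-consistent, which is what lets the
full pipeline (delineation → geodesics → fit) recover `(a, b)` to < 1 %
noiselessly; residual error is mesh discretization, not the optimizer.

Species presets (all overridable):

| parameter | human | macaque | meaning |
|---|---|---|---|
| `cmf_a` | 1.0° | 0.8° | ground-truth magnification scale |
| `cmf_b` | 0.063 /mm | 0.12 /mm | ground-truth magnification rate |
| `stimulus_radius` | 8° | 10° | stimulated field (16° / 20° diameter) |
| `v1_extent_mm` | 34.8 mm | 21.7 mm | radial extent of the sheet |
| `lateral_extent_mm` | 28 mm | 20 mm | transverse arc at mid-eccentricity |
| `rcas_band` | 2–5° | 7–10° | eccentricities of the rCaS fold |
| `ecas_band` | 0–1° | 1–4° | eccentricities of the eCaS fold |

The rCaS bands are the anatomically reported posterior/anterior lip
eccentricities for each species; the eCaS bands are generator choices
informed by reported mean eccentricities near 0.4° (human) and 2.5°
(macaque). The ground-truth `(a, b)` values are generator defaults chosen
so V1 spans the stimulated field over realistic cortical extents — they are
not empirical claims. `v1_extent_mm` is set to (just under)
`d(stimulus_radius)` so the map spans the stimulated field without
truncation; fold depths (human calcarine 3.5 mm, rCaS 2.5 mm, eCaS 1.5 mm;
macaque 2.5/0.7/2.0 mm) are within what each fold's width admits for this
corrugation family. The calcarine trough runs along the full length of the
sheet with depth scaled by radius (a conical trough), keeping the short
foveal arc nearly flat instead of cutting it with full-depth walls.

Sulcal labels are the fold flanks: vertices whose profile tangent exceeds
`label_tilt_deg` (15°), restricted to the fold's eccentricity band. This
gives curvature-correlated labels like real sulci without simulating
morphogenesis.

**Measurement noise** (`add_measurement_noise()`): wrapped-Gaussian polar
angle noise (default sd 8°), multiplicative log-normal eccentricity noise
(default sd 0.1), and vertex dropout (default 5 %), with a coherence
overlay that decreases with the injected noise. In addition, the cohort
driver applies a seeded log-normal jitter (sd 0.1, clamped to a feasible
[0.85, 1.05] factor) to each subject's fold depths: without anatomical
variability every subject of a species has identical sulcal morphometry
and a between-subject ANOVA on areas or %V1 is degenerate (zero residual
variance). Only depths are jittered, so all subjects of a preset stay on
a common grid and group overlap maps remain well-defined without surface
registration. These defaults emulate the
scatter of single-vertex retinotopic estimates; they do **not** reproduce
the spatial autocorrelation, coherence structure, or pRF-fit biases of real
fMRI, so passing tests demonstrate the pipeline's correctness and
robustness at realistic noise magnitudes, not instrument realism.

**Time series** (`generate_timeseries()`): phase-encoded traveling waves —
wedge runs of 8 cycles × 40 s, ring runs of 7 cycles × 40 s with 10 s
blanks inserted to separate foveal from peripheral responses — sampled at
1 s, with a fixed hemodynamic delay and additive Gaussian noise. Ring
sweeps are linear in eccentricity by default (a log sweep is available);
the wedge sweep starts at the contralateral horizontal meridian. Blank
periods contribute baseline signal. No hemodynamic impulse-response
convolution beyond the fixed delay is modeled.

## Phase mapping

`fourier_phase()` estimates, per vertex, the amplitude and phase of the
response at the stimulus frequency by joint least squares on
`{1, t, cos ωt, sin ωt}`. A detrend-then-DFT sequence leaks trend energy
into the stimulus bin (~1e-3 rad of phase error even noiselessly); the
joint regression is exact for a pure harmonic. Coherence is the DFT
amplitude at the stimulus frequency over the root-sum-square of all
non-DC, non-trend bins (bins 0 and 1 cycle/window excluded), and blank
periods are excluded from the analysis window by default (the samples of
each cycle's stimulus period concatenate continuously in stimulus time).

`combine_directions()` takes the circular half-difference of
opposite-direction phase maps, cancelling any delay common to the two
directions. The half-difference is only defined modulo π — adding half a
cycle to both the position and the delay is an exact symmetry — so the
ambiguity is resolved by assuming the common delay is below a quarter
cycle (10 s), which covers physiological hemodynamic delays.
`phase_to_visual()` maps the delay-free phase linearly onto the sweep
range and marks vertices below a coherence threshold (default 0.25)
invalid; the threshold is a declared package default, not an empirical
constant.

## Delineation

Border detection bands vertices within `tol_deg` (default 10°) of ±90°
after one pass of circular 1-ring smoothing of the polar-angle map
(`smooth_iters = 1`; 0 disables). The band is dilated by one ring when
finding its largest connected component and the border path may traverse
those connector vertices — this bridges cuts caused by vertex dropout —
but the band criterion and the endpoints stay strict. The path from the
band's lowest- to highest-eccentricity vertex (ties broken toward the
meridian) uses edge weights `length × (1 + dev/tol_deg)` so it hugs the
meridian; on noiseless synthetic subjects it reproduces the generator's
±90° rows exactly.

The confluence line is the shortest path between the borders' foveal
endpoints under weights `length × (1 + E_mid/E_scale)` (`E_scale` = 1°), a
quantitative surrogate for "a curved line through the most foveal
measurements"; a warning is logged if the line rises above the 5 %
eccentricity quantile of V1 by more than 0.5° (common under noise, where
the foveal vertices' measured eccentricities scatter). Distance from the
fovea is the multi-source edge-graph geodesic from the whole line
(`mode = "line"`); `mode = "midpoint"` reproduces the single-point
variant, and the two fields correlate > 0.99 on synthetic subjects. When
no V1 hint is given, V1 is the connected set of valid vertices inside the
stimulus-radius eccentricity isoline containing the confluence line plus
the border paths.

## Numerical choices

- **Geodesics** are Dijkstra shortest paths on the edge graph (edge weight
  = Euclidean length), not exact polyhedral geodesics. On a grid with both
  diagonal directions the worst-case overestimate is 1/cos(22.5°) ≈ 8.2 %,
  and distances along mesh axes from a line source are exact; the test
  suite asserts the ≤ 9 % bound. Unreachable vertices are flagged invalid.
- **Areas** attribute one third of each triangle to each corner vertex, so
  subset areas are additive over partitions to machine precision.
- **Histogram** bins are half-open, anchored at 0 (first bins [0, 0.5)° ×
  [0, 1) mm). Isocontours are traced by `grDevices::contourLines` (a
  marching-squares level-set tracer) on the per-sulcus count grid padded
  with a zero ring so contours close around boundary cells; the 99 % level
  is kept even though it typically yields a tiny contour around the mode.
- **ANOVA**: balanced designs use classical sums of squares; unbalanced
  designs (such as 24 vs 6 subjects) use Type II (`car::Anova`), the
  choice recorded in the result. Constant data decompose to F = 0 exactly.
  Hemispheres enter as independent observations, giving `df_den = n - 4`
  for the 2 × 2 design; with 30 subjects × 2 hemispheres that is F(1, 56).
  This replicates the conventional analysis and is a documented caveat —
  a mixed model treating subject as a random effect would be more
  conservative. No multiple-testing correction is applied by default.
- **Units** are carried on overlays (`deg`, `mm`, `rad`, `unitless`) and
  checked at operation boundaries; mixing units raises an error.
- **Indexing**: vertex indices are 1-based inside R (language idiom);
  FreeSurfer/GIFTI/CSV files store 0-based indices, converted at the file
  boundary. A 1-based CSV dialect must be declared (`one_based = TRUE`).
- **Determinism**: every stochastic operation takes a seed; the cohort
  driver derives per-subject seeds from the master seed and writes md5
  content hashes of its outputs to a manifest.

## Problem sizes and what the tests show

Default resolution is 2 vertices/mm, giving ~4,000-vertex human and
~1,800-vertex macaque patches; the validation cohorts use 24 human + 6
macaque subjects × 2 hemispheres, and robustness properties are swept over
20 seeds. These sizes keep a full cohort under a few minutes on one core
while leaving mesh discretization error well below the tolerances being
tested. The suite demonstrates: exact-oracle agreement for areas,
geodesics, isocontours and ANOVA; noiseless end-to-end identity for phase
decoding and delineation; < 1 % noiseless and < 5 % median noisy recovery
of `(a, b)`; and the qualitative species contrast (macaque rCaS more
eccentric than human rCaS, eCaS more foveal than rCaS within species) in
every seeded cohort. What they do not show is performance on real fMRI
maps: border placement there was done by expert inspection, and no
quantitative reversal criterion can replicate an anatomist's judgment.

## Known limitations

- Edge-graph geodesics overestimate off-axis distances by up to ~9 %; exact
  polyhedral geodesics are out of scope by design.
- The generator's folds are kinematic corrugations, not biomechanical
  folding; its noise is spatially independent.
- The wedge decode assumes the full 360° sweep convention; hemifield
  sweeps would need a declared sweep range.
- Group overlap maps require subjects on a shared template grid;
  cross-subject surface registration is out of scope (synthetic subjects
  of one preset share their grid by construction).
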