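# sulcmap

Quantifying how occipital sulci relate to the retinotopic map of primary
visual cortex (V1), across species.

## The problem

V1 maps the visual field continuously: eccentricity *E* (degrees from
fixation) grows along the length of V1, polar angle varies across it, and
the V1/V2 border lies at vertical-meridian representations. Two folds — the
**retrocalcarine sulcus (rCaS)**, the vertical posterior termination of the
calcarine sulcus, and the **external calcarine sulcus (eCaS)** on the
lateral occipital surface — sit at characteristic places in this map that
differ sharply between humans and macaques. `sulcmap` is for researchers in
computational neuroimaging who want to measure that relationship on
cortical surface meshes: it delineates V1 from polar-angle reversals,
builds the foveal confluence line, computes surface geodesic distances,
fits the cortical magnification function

    E = a (exp(b * d̂) − 1)

(where `d̂` is cortical distance in mm from the foveal confluence, `a` in
deg and `b` in 1/mm are free parameters; the −1 forces E(0)=0 so foveal
measurements can be fit), characterizes each sulcus with 2D
eccentricity-by-distance histograms and 99/75/50/25 % isocontours,
summarizes per-sulcus areas, %V1 and visual-field coverage, and runs
species × hemisphere ANOVAs.

Because the datasets this analysis is usually performed on are
restricted-access, the package includes a first-class synthetic folded-V1
generator (human and macaque presets, ground-truth retinotopy, measurement
noise, and phase-encoded traveling-wave time series — wedge 8 × 40 s, ring
7 × 40 s with 10 s blanks) used to validate every stage end to end. File
IO covers FreeSurfer binary surfaces/curv/label, GIFTI
(`.surf.gii`/`.func.gii`/`.label.gii`), CSV overlays, and JSON label sets.

## Worked example

Simulate one macaque hemisphere at default measurement noise, run the full
analysis, and look at the magnification fit and the two sulci:

```r
library(sulcmap)
res <- simulate_subject("macaque", seed = 3)
res$fit
#> <cmf_fit: E = 0.7718 (exp(0.1222 d) - 1), r2 = 0.9783, n = 1705>
res$summaries[, c("sulcus", "area_pial", "pct_of_v1", "mean_ecc",
                  "ecc_min", "ecc_max")]
#>   sulcus area_pial pct_of_v1 mean_ecc ecc_min ecc_max
#> 1   rCaS      83.2      19.3     8.38   5.884   12.26
#> 2   eCaS     119.9      27.8     2.25   0.965    4.19
```

The fit recovers the generator's ground truth (a = 0.8°, b = 0.12 /mm)
from noisy data with r² ≈ 0.98; the rCaS mean eccentricity (8.38°) falls
inside its generating 7–10° band and the eCaS (2.25°) inside 1–4°,
reproducing the macaque pattern in which the rCaS marks mid-peripheral and
the eCaS near-foveal visual space. A cohort run aggregates this over
subjects and tests the species contrast:

```r
res <- run_pipeline(default_config(n_human = 24, n_macaque = 6, seed = 1))
res$anovas$rCaS.mean_ecc     # species x hemisphere ANOVA, Type II SS
group_table(res$summaries, "mean_ecc")
```

The numbered scripts under `analysis/` walk through the same stages as a
narrative workflow (simulate → phase-map → fit → summarize → compare) and
write their tables under `results/`.

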