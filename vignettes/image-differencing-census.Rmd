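---
title: "Counting animals by single-day image differencing: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Counting animals by single-day image differencing: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(pasturediff)
```

## The model and its assumptions

The pipeline treats a pair of same-day acquisitions of one pasture as two
samples of an almost-static scene perturbed by moving animals. Its premises:

- **Static background.** Vegetation, soil and built features do not move or
  change reflectance appreciably between acquisitions (minutes to a few
  hours apart). Every persistent difference is then attributable to sensor
  noise, illumination drift, mis-registration — or animals.
- **Compact movers.** An animal occupies a compact footprint of roughly
  1–3 m² and, given enough elapsed time, moves farther than its body length,
  leaving two disjoint change patches (the vacated and the newly occupied
  position).
- **Common geometry.** Both rasters sit on a common 0.25 m pixel lattice in
  planar map meters. Registration residuals are small relative to an animal
  (the package measures them; it does not assume them away).

PC1 is used instead of any single band because the three bands are strongly
correlated over grassland; the leading component concentrates the shared
signal and a single threshold can then be applied to one difference layer
rather than three.

## Processing choices that needed a decision

Several steps admit more than one defensible definition. The package fixes
each one explicitly:

- **Covariance PCA, per image, after clipping.** Bands share one physical
  unit, so the covariance (not correlation) matrix is decomposed — the
  remote-sensing default for same-unit bands. Both decompositions are
  computed on the *clipped* common extent so they see identical spatial
  support; statistics use valid (unmasked) pixels only.
- **Eigenvector sign.** The sign of each loading vector is fixed so that its
  loadings sum positive (tie: first nonzero loading positive). Without a
  convention, an arbitrary flip between the two decompositions would turn
  "no change" into maximal change.
- **Pixel conventions.** 0-based indices, north-up grids, pixel-center
  coordinates for points, half-open pixel footprints `[x, x+s) × (y−s, y]`
  (a point on a shared edge belongs to the higher column / lower row). One
  unambiguous convention removes ±half-pixel drift between modules.
- **Inclusive thresholds.** Spectral bounds are inclusive at both ends; the
  area filter keeps `0.99 ≤ area ≤ 10` m² inclusively, because the removal
  rules are the strict inequalities (> 10, < 0.99). At 0.25 m pixels the
  boundary cases are exactly 15 px (0.9375 m², removed) vs 16 px (1.0 m²,
  kept) and 160 px (10.0 m², kept) vs 161 px (10.0625 m², removed).
- **8-connectivity by default.** Animal blobs imaged through a point-spread
  function produce diagonal pixel chains that 4-connectivity would split
  into spurious multiple detections; both modes are available and tested
  against an independent graph-based labeling oracle.
- **Unsmoothed polygonization.** Boundaries trace exact pixel edges
  (edge-cancellation plus a left-turn-priority walk, so a diagonal pinch
  stays on one ring); enclosed area always equals pixel count × pixel area,
  which the tests assert by shoelace computation. Output polygons are sorted
  by (min row, min col) so runs are diffable.
- **Threshold suggestion.** The heuristic "find values associated with known
  animals" is formalized as: pool the difference values in 3×3-pixel windows
  around every animal's T1 and T2 positions and take the 5% order statistic
  (`type 1` quantile) as `t_low`. The percentile is an explicit parameter
  and a manual threshold can always be supplied — the step stays
  *semi*-automated by design.
- **Matching and scoring.** A polygon is eligible for an animal when it
  contains, or lies within `r_match = 1` m (about half an adult cow body
  length) of, either the T1 or the T2 position; assignment is greedy by
  increasing distance with deterministic tie-breaks; each animal is credited
  once, each polygon at most twice ("dual" polygons). An animal's second,
  uncredited footprint therefore counts as commission — this keeps
  `known = detected + missed` exact. `P_correct` counts credited *animals*,
  `(correct + dual)/known`; the polygon-count variant is also exposed as
  `p_correct_polygon`. Percentages are rounded half away from zero, and
  cross-pasture means are taken over unrounded ratios.

## The synthetic generator

`scene_config()` / `generate_scene()` emulate what the method needs from
real imagery, with defaults chosen once for a late-autumn senescent
grassland at 0.25 m resolution:

| parameter | default | rationale |
|---|---|---|
| extent | 250 m (6.2 ha) | typical fenced-pasture size in the validation design |
| background mean (g/r/nir) | 0.13 / 0.14 / 0.30 | senescent grass: red edge flattened, moderate NIR |
| texture | multiplicative, cv 0.15, 1 m correlation | tussock-scale spatial structure |
| animal offsets (g/r/nir) | −0.06 / −0.07 / −0.18 | dark livestock against grass |
| animal contrast factor | U(0.5, 1) per animal | coat variation (black to light brown) |
| footprint area | U(1.2, 3.0) m², aspect 1.5–2.5 | adult cow/horse seen from above |
| movement | U(2, 20) m, uniform direction | grazing displacement over 1–2.5 h |
| shadow offsets | (0.9, 2.5) m at T1, (1.7, 2.0) m at T2 | a ~1.5 m tall animal under a low autumn sun whose azimuth moves between acquisitions |
| PSF blur | 0.5 px | camera point-spread |
| noise sd | 0.01 reflectance | sensor + minor illumination drift |

The background texture field is identical in T1 and T2 before noise (grass
does not move); mis-registration is injected by bilinear-resampling T2, so
its border pixels become nodata. Scenes are bit-reproducible from the seed;
suites derive per-pasture seeds as `base seed + index`.

What the generator does **not** emulate: BRDF and atmospheric effects,
realistic animal shapes and gaits, herd behavior (beyond an optional
minimum-separation constraint), sub-pixel mixed signatures beyond the
Gaussian PSF, and heterogeneous land cover (roads, water, shrubs). Passing
tests therefore demonstrate the pipeline's correctness and its qualitative
error structure, not field-accuracy guarantees on real imagery.

## The seeded studies

Two study functions drive the acceptance checks. Both use 150 m pastures
(2.25 ha, within the 1.9–9.7 ha range the method targets) with 13 animals,
over 20 seeds — sizes at which a full tri-condition run completes in a few
minutes on one core.

`study_clean_recovery()` configures the favorable regime: full animal
contrast, no PSF, no shadows, no mis-registration, movement 4–16 m (always
beyond body length), and 2.5 m minimum separation between different animals'
positions. The separation matters: if one animal's T2 position falls on
another's vacated T1 spot, the truth windows legitimately sample near-zero
differences and the suggested threshold collapses. The PSF is disabled here
because point spread is one of the method's documented error sources, not
part of the favorable regime. In this regime every animal should be
recovered and incorrect polygons are bounded by the herd size (one
uncredited duplicate footprint per animal, i.e. commission ≈ 50%).

`study_error_sources()` runs, per seed, a default-conditions baseline, the
same scene with a 1.06 m Y shift injected into T2 (the magnitude of residual
registration error a tie-point workflow leaves at this scale), and the same
scene with moving shadows enabled. For the mis-registration arm the spectral
threshold is held fixed at the baseline's value so the comparison isolates
the registration effect; re-deriving the threshold from a misregistered pair
additionally collapses it (the truth windows then sample misaligned
background), which is reported as a limitation rather than mixed into the
comparison. Shadows are thresholded per-condition, as an analyst would.

## Numerical details

- Registration is solved by QR least squares; a rank-deficient (collinear or
  duplicated) tie-point design is an error, not a warning. RMSE is reported
  in pixels of the target grid.
- Warping uses bilinear resampling; coordinates within 1e-7 px of an integer
  snap exactly, so identity and whole-pixel shifts are lossless and nodata
  does not bleed. Any contributing nodata neighbor makes the output pixel
  nodata.
- Grids must share a lattice to within 1e-6 m to be clipped or differenced.
- Eigenvalues are clamped at zero; orthonormality and trace conservation are
  asserted in tests at 1e-8.
- The GeoTIFF codec writes deterministic uncompressed float32 with
  ModelPixelScale / ModelTiepoint / GeoKey / GDAL-nodata tags (sentinel
  −9999); two writes of one image are byte-identical. Values round-trip
  exactly at float32 precision.
- An all-constant image (zero covariance) and an empty truth-window sample
  are errors with distinct classes, never silent zeros.

## Known limitations

- The spectral-threshold rule inherits the fragility of its inputs: truth
  positions in regions of genuinely low difference (animal swaps, occlusion,
  failed movement) drag `t_low` down and can flood the change mask. A
  robustified rule (e.g. trimming the window sample per animal) would be a
  natural extension.
- Commission from duplicate footprints is structural: without a temporal
  model the pipeline cannot tell a vacated position from an occupied one. A
  composite correction factor combining the three error rates is documented
  as future work, not implemented.
- The affine registration model assumes rigid flight-line geometry;
  higher-order polynomial warps would slot in behind the same interface.
- Percent-reflectance calibration is assumed done upstream; bands need only
  be unit-consistent within a run.
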