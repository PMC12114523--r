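---
title: "Measuring axon caliber from membrane-labeled images: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring axon caliber from membrane-labeled images: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(caliberkit)
```

## The measurement model

A membrane-localized fluorophore (e.g. an EGFP-CAAX fusion) labels the
plasma membrane of an axon but not its lumen. In an in-plane image of a
thin axon, an intensity profile taken perpendicular to the axon's axis
therefore shows two peaks, one per membrane, and the peak-to-peak distance
is the caliber at that location. `caliberkit` automates this line-scan
measurement and the morphometrics built on it: lengthwise pearling
profiles, branch-point symmetry and tapering, minutes-scale dynamicity, and
the analyses of axons crossing dividing basal skin cells.

The measurement chain for one station is:

1. **Geometry.** The annotated polyline is resampled at a fixed arc-length
   step (0.05 µm) with central-difference tangents smoothed over 0.5 µm;
   the normal is the tangent rotated by 90°. The 0.5 µm window suppresses
   annotation jitter at the resampling scale without erasing curvature at
   the scale of the measurements (stations are ≥ 1 µm apart).
2. **Profile extraction.** Bilinear interpolation of the axon channel at
   offsets `−L..L` (default half-length `L` = 1.5 µm, spanning the largest
   observed calibers with margin) with spacing of half a pixel. Following
   the wide-line convention of interactive profile tools, pixel-spaced
   parallel lines within `scan_width_um` (default 0.2 µm) of the station
   are averaged along the local axis; an axon is locally straight and of
   locally constant caliber at this scale, so averaging reduces shot noise
   without biasing the peak separation.
3. **Peak detection.** Local maxima are screened by topographic prominence
   (≥ 15 % of the profile's intensity range) and height (≥ 50 % of the
   range above the profile minimum); among qualifying maxima, the one
   nearest the centerline on each side is selected. Nearest-first selection
   rejects crosstalk from neighboring axons further out; the height screen
   rejects background noise ripples far from the axon, which can be locally
   prominent yet dim. Before screening, the profile is smoothed with a
   0.01 µm Gaussian — an order of magnitude below the PSF width, so peak
   positions move negligibly.
4. **Sub-sample refinement.** Each selected peak is refined by the vertex
   of a least-squares quadratic over up to 7 samples, with the window
   shrunk near the centerline so it never straddles the saddle of a
   barely-resolved pair; a 3-point parabola is the degenerate fallback.
   The wider fit roughly halves the localization noise of the classic
   3-point parabola at these signal levels.
5. **Flagging.** A station is flagged *below limit* when no qualifying peak
   pair exists (unresolved) or when the measured caliber falls below
   `resolution_limit_um`. Flagged measurements are retained in output
   tables for transparency but excluded from every summary. A time series
   whose flagged fraction exceeds 0.20 (strictly) is excluded outright; a
   series with exactly 20 % flagged is kept.

### Parameters that matter

| Parameter | Default | Units | Rationale |
|---|---|---|---|
| `resolution_limit_um` | 0.14 | µm | ≈ 2 × the default PSF σ: below this the two membrane images merge. Configurable because it is a property of the user's optics. |
| `scan_half_length_um` | 1.5 | µm | covers calibers up to ~1.5 µm, the top of the observed in vivo range |
| `scan_width_um` | 0.2 | µm | 5 pixel-spaced parallel lines; shot-noise averaging over a locally straight span |
| `branch_offsets_um` | 3, 4, 5 | µm | segment caliber = mean over these offsets from the branch point |
| `lengthwise_interval_um` | 1 | µm | station spacing of lengthwise profiles |
| `branch_exclusion_um` | 3 | µm | stations strictly closer than this to a branch point are dropped; a station at exactly 3 µm is kept (literal reading of the "< 3 µm" rule) |
| `below_limit_series_fraction` | 0.20 | — | strict `>` exclusion rule for time series |
| `min_prominence_frac` | 0.15 | — | membrane peaks are the dominant structure of a centred scan |

Offsets from branch points are walked **along the path** (geodesic), not
straight-line: in curved arbors the 3–5 µm offsets follow the axon's
course, and the along-path rule is the reproducible convention. A
`straight_line` mode is available as a configuration switch.

During time lapses, stations are re-anchored each frame when per-frame
centerlines are supplied; a single centerline falls back to fixed scan
lines. Re-anchoring is the default because tissue drift, not axon motion,
dominates frame-to-frame displacement at 5-minute intervals.

## Derived metrics

With segment calibers `P` (primary), `S1 ≥ S2` (secondaries, ties broken by
annotation order and flagged):

- normalized calibers `S1/P`, `S2/P`; symmetry `S2/S1`, which equals
  `(S2/P)/(S1/P)` identically;
- cross-sectional areas `π(c/2)²`; tapering area ratio
  `(area_S1 + area_S2)/area_P`, which equals `(S1² + S2²)/P²` because π/4
  cancels;
- radius scaling ratios `S1/P`, `S2/P`, also pooled across both
  secondaries of every branch point into one sample.

Dynamicity at a station is the sample SD of caliber across frames
(absolute) and `%RSD = 100·SD/mean` (relative). Pearling is the sample SD
of caliber across 1 µm stations. Sample SD (n − 1) and SEM = sd/√n are
used throughout, consistent with small per-series n.

For the dividing-cell analyses, the *round* and *flat* frames are the
consecutive pair with the largest increase in border-to-border length (ties
take the earliest pair, flagged); stations are grouped by polygon
containment of their centerline point, with boundary ties assigned to the
dividing cell for determinism. The axon path over a rounded cell is
modeled as a circular arc through the chord endpoints: with chord ℓ and
sagitta h, `R = (ℓ²/4 + h²)/(2h)` and `arc = 2R·asin(ℓ/(2R))` (continuous
limit `arc → ℓ` as `h → 0`; the major arc is used when `h > ℓ/2`). The
circular segment is the minimal two-parameter shape consistent with the
height-and-length estimates the model is built from; an elliptical variant
can be substituted by the caller because the function is pure geometry.

## The statistical layer

- **Paired sign-flip permutation test.** The statistic is the mean of the
  paired differences. All `2^n` sign assignments are enumerated for
  n ≤ 20; otherwise a seeded Monte Carlo draw (default 10,000) includes
  the observed assignment in numerator and denominator (`(b+1)/(B+1)`), so
  p is never zero. Two-sided throughout.
- **Mann–Whitney U** with midranks for ties; exact two-sided p by
  enumerating all `choose(n+m, n)` labelings for n + m ≤ 14 (tie-aware),
  else a normal approximation with tie-corrected variance and continuity
  correction. The exact-mode thresholds keep enumeration sub-second.
- **Paired mean difference CI** by seeded bootstrap over pairs (default
  5,000 resamples), bias-corrected-and-accelerated with jackknife
  acceleration; when the bias correction or acceleration is undefined the
  percentile interval is used, and the method actually applied is recorded
  in the result.
- **OLS regression** via `stats::lm`, reporting slope, intercept and R².

No multiple-testing correction is applied; the analyses are reported
comparison-by-comparison.

## What the phantom generator emulates — and what it does not

The generator renders the membrane as an infinitely thin label sheet at
`±c(s)/2` along the centerline normal — two curves in 2-D — sampled at
0.01 µm steps, deposited by bilinear splatting with line-integrated label
density, convolved with an isotropic Gaussian PSF (default σ = 0.07 µm, a
super-resolution-class lateral width), then degraded with Poisson noise on
signal + background and Gaussian read noise (defaults: 200 photons/µm of
membrane, background 10, read noise SD 2). The PSF kernel is normalized to
unit peak, so `photons_per_um_membrane` states the full transverse
line-spread integral contributed per micrometre of membrane; with the
default settings a membrane line peaks at ≈ 35 counts over the background
of 10, a realistic mid-SNR regime. Ground truth `c(s)` (and `c(s, t)` for
time lapses) is exported at 0.1 µm steps, so recovery can be scored
exactly. Pearls are additive Gaussians **on caliber**, not on intensity,
precisely so that ground truth is stated in the units being recovered.

Time-lapse scenes compose four event classes — a traveling pearl, focal
inflation/deflation, segment-wide widening/narrowing, and a transient
constriction point — on top of the resting profile. A companion generator
prescribes the per-frame baseline directly, for dynamicity studies where
the series' ground-truth %RSD must be exact. In validation, high-RSD series
use an upward-skewed fluctuation pattern (transient dilations over a steady
resting caliber) so that even a 60 % RSD series stays above the resolution
limit; symmetric fluctuations of that magnitude would clip at the
unresolvable floor, which is a property of the optics, not of the
estimator being validated.

The dividing-cell scene renders three rectangular basal-cell territories
(bright border polygons in a second channel) with the central cell's
border-to-border length following a per-frame schedule from its rounded
length to its flat length, an axon crossing all three cells, a configurable
caliber offset on the dividing cell, and a deflation ramped with the
flattening progress. The default axon baseline is 0.22 µm so that the
dividing-cell caliber sits at 0.28 µm (round) and 0.25 µm (flat) — a thin,
skin-embedded regime that remains above the default resolution limit.

What the phantoms deliberately do **not** model: 3-D optics and optical
sectioning (the measurement is in-plane peak separation, so a 2-D image
model suffices), photobleaching, axon growth and branch formation,
non-Gaussian PSF tails, sample drift, and neighboring-axon crosstalk.
Passing the recovery tests therefore shows that the estimator is accurate
for resolvable, well-annotated, in-focus axons; it does not certify
performance on out-of-focus data or poor annotations, where the
below-limit flags and the quality column are the first diagnostics to
inspect.

## Numerical choices and degenerate inputs

- Image coordinates are `(x, y)` in µm with the origin at the **centre** of
  pixel (row 1, col 1); all module boundaries speak µm and minutes, never
  pixels.
- Calibration is never guessed: reading a TIFF requires a sidecar or
  explicit pixel size, and a conflict between the two is an error.
  Stack writes pre-quantize onto the writer's 32-bit integer grid so that
  write/read round trips are idempotent (the first write is exact for
  counts below 2^24; subsequent trips are bit-identical).
- Results CSVs use `.` decimals, UTF-8, stable column order and 15
  significant digits (round-trips to ≤ 1e-9 at these magnitudes).
- Unresolved peak pairs are a *value* (`resolved = FALSE`), not an error;
  all-flagged series carry an explicit `all_flagged` status.
- Degenerate statistics are flagged rather than invented: all-zero
  differences give p = 1, a constant bootstrap sample gives a zero-width
  CI, and a constant regression response gives R² = 0 with a flag.
- `select_round_flat` on a never-increasing schedule returns the
  least-negative change with a warning.

## Validation problem sizes

The test suite and the acceptance script validate on: six true calibers
{0.2, 0.3, 0.5, 0.8, 1.2, 1.5} µm × 20 interior stations (pixel 0.04 µm,
PSF σ 0.07 µm, default noise); five sub-resolution (0.08 µm) phantoms;
branch triplets around (0.43, 0.32, 0.20) µm; 12-frame dynamicity series at
10/30/60 % RSD; 2,000 null simulations for the permutation test's type-I
error; 500 datasets × 5,000 resamples for bootstrap coverage; 200 seeded
null dividing scenes for the Mann–Whitney uniformity check; and a 10⁶
segment polyline oracle for the arc model. These sizes give tight Monte
Carlo error on every check while keeping the default validation run in the
minutes range on a single core.

## Known limitations

- The measurement is in-plane: axons tilted steeply out of the imaging
  plane foreshorten, and no 3-D correction is attempted.
- Centerlines come from annotations (human or simulator); there is no
  automatic skeletonization, and grossly mis-drawn centerlines shift the
  scan geometry.
- At calibers within ~1.5 × the resolution limit, a growing fraction of
  stations is flagged rather than measured; summaries over the surviving
  stations are accurate but can be subtly selection-biased, which is why
  the series-level exclusion rule exists.
- The circular-arc path model is a two-parameter idealization; real
  rounded cells are neither circular in section nor constant along the
  crossing axon.
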