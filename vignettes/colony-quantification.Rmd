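---
title: "Colony formation quantification: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Colony formation quantification: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(colonyquant)
```

## The measurement model

A crystal-violet-stained well scanned on a flatbed scanner presents dark
cell colonies on a light background. After conversion to 8-bit greyscale,
the package reduces each well to two statistics computed on a *density
image* — the well after background thresholding and inversion, where
background pixels are 0 and cell pixels carry `255 − intensity` (1 to 255):

* **colony area percentage**: `100 · #(density > 0) / #(region pixels)` —
  the covered fraction of the analysed region;
* **colony intensity percentage**: `100 · Σ density / (255 · #(region
  pixels))` — coverage weighted by staining density, normalised to full
  saturation. It is bounded above by the area percentage, with equality
  when every cell pixel is completely dark.

Region denominators always count the circular analysis mask intersected
with any sub-region rectangle — pixels outside the analysis disc never
enter numerator or denominator. Avoiding per-colony segmentation is the
point: no colony counting, no touching-colony heuristics, no size
integration.

## Well geometry

Wells are located by arithmetic alone: the user supplies one rectangle
enclosing a contiguous block of wells, and centres are placed on a uniform
row × column lattice filling it. The nominal well radius is
`(well_diameter / well_pitch) × (smaller lattice span) / 2`, from built-in
plate dimensions (6-well: 34.8/39.12 mm, 12-well: 22.1/26.01 mm, 24-well:
15.6/19.3 mm — typical manufacturer values, all overridable). No
image-based circle detection is attempted; the mapping is therefore
deterministic and independent of staining level, but assumes an unrotated,
evenly spaced rectangular plate.

Each analysis disc is the nominal disc with its **diameter scaled once by
0.95** (`crop_fraction = 0.05`), excluding the well rim where cells grow
abnormally. The phrase "reduce the diameter by 5%" could also be read as 5%
off each edge (10% total); we take the single-scaling reading and expose
`crop_fraction` for sensitivity analysis. Disc membership uses the
half-open rule `dx² + dy² < r²` evaluated at pixel centres (origin
top-left, x rightward, y downward), so masks at a larger crop fraction are
strict subsets of masks at a smaller one.

## Background threshold detection

For a well with masked pixels `p`, define `A(t)` = percentage of pixels
with intensity ≤ t (t = 0…255) — the colony area percentage as a function
of an applied threshold, i.e. the cumulative histogram. `A` rises through
the cell mode, flattens across the gap, then jumps towards 100% as the
threshold starts swallowing the background mode. The background threshold
is the end of the flat stretch: the last intensity at which only cells are
selected.

Numerically:

1. `dA` and `d2A` are backward differences (`dA[0] = A[0]`).
2. `dA` is smoothed with a centred moving average of window 3 before
   extremum detection (the raw `dA` is kept on the object; the smoothing
   scheme is a package choice — only the smooth curves themselves are
   standard).
3. The **background peak** is the global maximum of the smoothed `dA`;
   ties resolve toward *higher* intensity, because the background is by
   construction the high-intensity mode (with two equal spikes, e.g. half
   the pixels at 50 and half at 250, the high one is the background).
4. The **valley** is the deepest minimum of the smoothed `dA` below the
   peak; among equally deep candidates the one at the *highest* intensity
   wins — the plateau edge nearest the background mode, equivalently the
   last negative-to-positive zero crossing of `d2A` before the background
   rise. On a perfectly bimodal well this lands just below the background
   mode; on a well with an empty gap it lands at the gap's upper edge.
5. If the valley carries no cell mass (`A(valley) ≤ min_cell_area`,
   default 0), the well is reported as `no_colonies` with the threshold at
   the largest t where `A` is still 0; both statistics are then 0. This is
   a result state, not an error.

Choosing the *deepest* minimum (rather than the local minimum nearest the
peak) makes the rule immune to sampling wiggles inside the background
mode: multinomial fluctuations create shallow local minima there, while
the true cell/background gap is systematically the emptiest stretch of the
histogram. The trade-off is discussed under *Limitations*.

The assumption behind step 3 is that the background is the per-bin
dominant mode — true of real scans, where the empty well is a bright,
narrow intensity peak while stained cells spread over a wide range of dark
values. A well in which a single uniform colony intensity out-masses the
background peak would be mis-oriented by this rule; the cross-well
consistency check is the systematic defence.

## Cross-well consistency check

`A(t)` can carry several local minima, so a threshold found in isolation
is occasionally wrong. All wells of a plate are therefore compared on a
common footing:

1. each well's threshold is linearly rescaled as if the well's maximum
   intensity were 200 (`scaled = t × 200 / max_intensity`), countering
   non-uniform illumination; scaled values stay real-valued during
   comparison and are rounded (half-up) only when mapped back;
2. the plate mean of the scaled thresholds is taken over *all* wells
   (flagged ones included; `exclude_flagged = TRUE` recomputes the mean
   without them for one extra pass);
3. wells deviating by more than `tolerance` (default 50) scaled units are
   flagged and re-thresholded with the search restricted to
   `mean ± tolerance`, mapped back to native intensities; re-evaluated
   wells carry `method = "restricted"`.

The restricted re-detection re-runs the full derivative analysis inside
the window. The operation is idempotent in practice: re-evaluated
thresholds land inside the window, so a second pass re-evaluates nothing
(verified by test).

## Dose-response fitting

`fit_ll4()` fits `y = c + (d − c) / (1 + exp(b(ln x − ln e)))` by
Levenberg–Marquardt nonlinear least squares on raw replicate points (not
dose means). Start values: `d₀` = max response, `c₀` = min response, `e₀` =
dose nearest the half-range crossing, `b₀ = 1`; `e` is bounded to
`[min dose/10, max dose × 10]`. Standard errors come from the estimated
parameter covariance; `ic50()` returns `e` and its SE. Zero-dose controls
are excluded (`ln x` undefined); `anchor_upper = TRUE` instead fixes `d`
at the control mean. Constant responses raise a fit error ("no dose
effect") rather than returning a degenerate model.

One calibration fact worth knowing: at a realistic design (8 doses from 2
to 100 concentration units, quadruplicates, noise 5% of the upper limit)
the sampling distribution of the IC50 estimate is visibly right-skewed —
the median estimate sits within half a percent of the truth while the mean
is pulled several percent upward by occasional shallow-curve fits whose
global least-squares optimum genuinely lies at a large `e` (checked
against a multistart oracle). The ±3·SE interval still covers the true
value in ≥ 95% of seeded repetitions; per-fit SEs should nevertheless be
read as local curvature, not as symmetric error bars.

`pearson_correlation()` provides the product-moment correlation with the
OLS regression line for comparing read-outs (area vs intensity percentage,
or either against an external absorbance column).

## The synthetic generator

`render_plate()` emulates exactly the features the pipeline keys on:
a uniform light background inside circular wells (default intensity 220),
darker inter-well plastic (140), colonies as non-overlapping discs with
per-colony uniform intensity drawn from a dark range (default 60–110;
Gaussian-profile colonies behind `profile = "gaussian"` for harder tests),
optional one-sided shading and additive Gaussian noise (rounded, clipped
to [0, 255]). Colonies are placed by rejection sampling until the target
coverage is met, overshooting by at most one colony; a jammed placement
(target beyond what the radius range can pack) is an error. Ground truth
is counted on the *rendered* raster inside the same analysis mask the
pipeline uses, so on clean plates the measured area percentage equals
truth to machine precision — the pixel-exactness tests exercise the whole
geometry/threshold/measure chain, not a simplification of it.

The default rendering resolution in tests is 120–300 dpi: the method is
resolution-independent (truth is defined on the same raster), so tests use
sizes that keep the suite fast; real scans should be ≥ 800 dpi as usual
for this assay.

Shading is a piecewise-linear darkening along x: zero up to
`shading_start` (fraction of width), then ramping over `shading_ramp` of
the width to the full amplitude (`shading_ramp = 0` gives a sharp shadow
edge, as cast by a lid or scanner edge). A sharp one-sided shadow
reproduces the classic failure mode: the detector locks onto the dominant
clean-background mode and places the threshold just beneath it, so the
shaded background — darker than the threshold — is called cells and the
full-well statistic grossly over-calls. Sub-region reanalysis of the clean
part (`measure_stack(..., region = ...)`, or `--subregion` on the CLI)
restores the true coverage, which is the recommended remedy; no
illumination-field correction is attempted. A *gradual* full-width
gradient behaves differently: either the histogram still separates (mild
amplitudes — no misclassification at all) or the smear destroys the valley
structure entirely, in which case manual thresholding is the fallback.

What the generator does **not** emulate: scanner vignetting PSFs, JPEG
artifacts, colony-shape irregularity, within-colony density gradients
other than the Gaussian option, well-rim growth (the pipeline crops it
away regardless), or plate rotation. Passing tests therefore demonstrate
algorithmic correctness on images with the assumed structure, not
robustness to every real-world scan artifact.

## Numerical conventions

* All intensity conversions round **half-up** (`floor(x + 0.5)`), applied
  consistently (RGB→grey means, 16-bit rescaling, scaled-threshold
  mapping, noise rounding).
* RGB→grey uses the unweighted channel mean `(r+g+b)/3` by default
  (Rec.601 luma available via `gray_method = "luma"`); grey triples are
  fixed points of either.
* 16-bit inputs are linearly min–max rescaled to 0–255 — a convenience
  extension; the analysis itself is defined on 8-bit data.
* "Cells" means intensity **≤** threshold (inclusive), everywhere.
  A threshold of 255 is rejected (it would classify saturated white as
  cells); `no_colonies` wells apply their threshold trivially (all-zero
  density).
* Percentages are kept at full double precision internally; the pipeline
  CSV reports 4 decimals, while `write_measurements(digits = NULL)`
  prints full precision and round-trips bit-exactly.
* Generators are pure functions of (parameters, seed) and restore the
  caller's RNG state.

## Test and validation sizes

The suite validates: the cumulative-histogram curve against a brute-force
per-threshold count; threshold detection on 100 seeded wells with disjoint
cell/background ranges (4000 pixels each) against an exhaustive
256-threshold scan, with pixel-exact coverage recovery; both statistics
against double-loop summation oracles on 1000 random density grids;
the consistency-check worked example (scaled thresholds 100/105/180,
tolerance 50 — flags exactly the third well) and its idempotence; LL.4
calibration over 200 seeded quadruplicate experiments (coverage of the
true IC50 within ±3 SE in ≥ 95%) and noiseless parameter recovery to
1e-3; and the full image pipeline on a rendered 24-well titration (8 doses
× 3 wells, IC50 recovered within 15%) plus the shading/sub-region remedy
(clean-part reanalysis within 2 percentage points of truth). The same
computations, regenerated from a seed, are what `scripts/acceptance.R`
reports.

## Limitations

* Geometry trusts the user's rectangle: no rotation correction, no
  automatic plate detection, one plate per image.
* The background must be the per-bin dominant intensity mode of each well
  (see above); extremely confluent wells (> ~50% coverage of a single
  uniform darkness) can invert the mode orientation. The consistency check
  catches isolated cases; plates of uniformly extreme wells need manual
  thresholds.
* Coverage targets above ~0.5 are not placeable by the hard-disc
  generator (random sequential packing jams); this bounds the synthetic
  study designs, not the analysis of real images.
* IC50 standard errors are within-fit (covariance-based); variability
  across biological repeats is a separate layer left to the user.
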