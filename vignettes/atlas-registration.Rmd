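---
title: "Atlas registration and multi-region quantification: methods"
author: "atlasquant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Atlas registration and multi-region quantification: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(atlasquant)
```

## The problem

Histological studies that relate labels of interest (immediate-early-gene
products such as c-Fos, perfused vasculature, amyloid plaques, ...) to
neuroanatomy need each 2-D tissue image delineated into named regions. A
curated atlas — a set of *plates*, each an ordered collection of named
polygon outlines traced against fixed reference dimensions — approximates
any individual brain only after per-image adjustment: tissue shrinks,
expands and distorts during processing. `atlasquant` implements that
workflow as a scriptable library: ImageJ-compatible ROI I/O, plate-to-image
registration, label segmentation, per-region measurement, and the
interrater-reliability statistics used to validate such registrations.

## Data model

The central objects are S4 classes. A `RoiRecord` is one named closed
polygon as stored in an ImageJ `.roi` record; an `AtlasPlate` is an ordered
list of `Region` outlines plus the reference width/height they were drawn
against; an `Atlas` is an ordered list of plates. Coordinates follow the
ImageJ convention: origin at the image top-left, x rightward, y downward;
pixel (row *r*, col *c*), 0-based, has center (*c* + 0.5, *r* + 0.5).

Regions within a plate **may overlap or nest** — custom atlas
organizations are deliberately unrestricted. Every measurement is
per-region independent, so an object or pixel inside two overlapping
regions contributes to both rows. Plates intended as partitions should be
drawn disjoint.

### ImageJ ROI format

`encodeRoi()`/`decodeRoi()` implement the stable core of the published
`.roi` byte layout (big-endian; magic `Iout`; type byte; int16 bounding
box and coordinate count; int16 vertex offsets; a second header carrying
the name as 16-bit characters). Only polygon (type 0) and freehand
(type 7) records are supported; every other type — line, oval, point,
composite — is rejected loudly rather than approximated, so composite
regions with holes cannot be silently flattened. Because vertex offsets
are int16, coordinates are quantized to the nearest integer *on write
only*; in-memory geometry stays floating point. Version-specific header
extensions are ignored on read and written as zeros: the core layout has
been stable across ImageJ versions, and none of the extension fields
affect polygon geometry or naming.

ROI-set ZIP archives are written uncompressed with a fixed timestamp, so
identical inputs give byte-identical archives; reading accepts compressed
archives from other tools.

## Registration

Registration fits a plate to a target image in two stages, mirroring a
coarse-then-fine manual workflow.

**Linear fit.** `linearFit()` rescales every vertex by
$s_x = W_\text{target}/W_\text{ref}$, $s_y = H_\text{target}/H_\text{ref}$.
Polygon (shoelace) areas scale by exactly $s_x s_y$; rasterized areas
scale the same way up to a discretization band proportional to the
perimeter.

**Free-form deformation.** Interactive tools let the user drag region
outlines; a scriptable library needs an explicit surrogate.
`freeformWarp()` takes control pairs $(\mathbf{s}_k \to \mathbf{d}_k)$ and
builds a smooth displacement field $W$ with $W(\mathbf{s}_k) =
\mathbf{d}_k$ exactly:

* 0 pairs — identity;
* 1 pair — global translation by $\mathbf{d} - \mathbf{s}$;
* 2 pairs — the unique similarity transform (rotation, isotropic scale,
  translation) through both pairs. Any affine interpolant of two pairs has
  zero thin-plate bending energy, so the family does not single one out;
  the similarity map is the canonical choice and is exact in closed form,
  whereas a pseudoinverse solve of the rank-deficient spline system
  reproduces the controls only to about $10^{-7}$ px — short of the
  $10^{-9}$ reproduction this module guarantees;
* $\geq$ 3 non-collinear pairs — thin-plate-spline displacement
  interpolation, kernel $U(r) = r^2 \log r$, with an affine term. The
  affine term makes exactly-affine pair sets reproduce their affine map at
  *every* point (verified to $10^{-6}$ px), and the interpolation
  conditions are solved exactly ($10^{-9}$ px at the controls). Collinear
  source points leave the affine part unidentified and are rejected.

The warp moves polygon **vertices only**; images are never resampled. A
long straight edge under a strongly nonlinear warp stays straight between
its endpoints, so outlines with sparse vertices should be pre-processed
with `densifyPolygon(maxEdgePx)` (off by default — typical hand-traced
outlines are already dense).

The default is one global warp per plate, which keeps shared boundaries of
adjacent regions coherent; `perRegion = TRUE` applies independent warps
per region for workflows that adjust each region separately.

Fitted plates are persisted per image (`exportFittedPlate()`) as ROI
archives plus a run log, enabling post hoc quality control and repeated
quantification of additional channels against the same registration.
`renderOverlay()` burns 1-px region outlines (outline = raster pixels with
a 4-neighbor outside) into an RGB copy of the registration channel;
`labels = TRUE` additionally burns region abbreviations with a built-in
3×5 bitmap font (off by default so the overlay alters exactly the outline
pixel set).

## Segmentation

`thresholdMask(image, lo, hi)` marks pixels with `lo <= value <= hi`
(closed interval, ImageJ threshold semantics, native intensity scale).
`sizeFilter(mask, min, max)` keeps connected components whose pixel count
lies in `[min, max]`; connectivity is 8 by default (ImageJ
particle-analysis convention) and configurable to 4. The size filter runs
globally, before regional measurement — the alternative (per-region
filtering after registration) would make an object's survival depend on
which region is being measured, which is harder to reason about and was
rejected. Externally binarized masks (e.g. from machine-learning
segmentation tools) enter through `coerceBinary()`, which accepts any
two-valued image and refuses anything else. No automatic threshold
selection is included: thresholds are per-label instrument settings chosen
by the analyst, and an auto-method would hide that choice.

## Quantification

`rasterizePolygon()` defines a region's pixel support: a pixel is inside
iff its center satisfies the even–odd (crossing-number) rule, with a
half-open tie-break (left/top boundaries in, right/bottom out) so that
abutting integer-coordinate regions partition the lattice without double
counting. The scanline implementation is checked exactly against an
independent per-pixel crossing-count oracle in the tests.

Per region, with $A$ = rasterized area (px², times µm²/px² when a pixel
size is supplied):

* **Object Counts mode** — $n$ = number of connected mask components whose
  exact centroid (mean of member pixel centers) lies inside the region
  polygon; density $d = n/A$ reported in objects/mm² only when the pixel
  size is known (never silently per-pixel). Centroid assignment counts
  each object at most once across disjoint regions and is deterministic;
  it can differ at boundaries from clip-based particle analysis, which
  splits straddling objects.
* **Volumetric Analysis mode** — percent area $p = 100\,L/A$ with $L$ the
  label-positive pixels inside the region raster. $A$ is the *rasterized*
  area, not the shoelace area, so numerator and denominator share one
  pixel lattice and $p$ is exactly 100 on the region's own raster.

Despite the historical name, Volumetric Analysis operates on single 2-D
planes (typically maximum-intensity projections); no z-handling is
implied.

## Interrater reliability

Given several raters' traces of the same regions:

* `percentOverlap(trace, ref)` = $100\,|T \cap R|/|R|$ on the pixel
  lattice — asymmetric containment; a symmetric Dice option exists
  (`dice = TRUE`). Lattice-based overlap matches the raster-based
  measurement workflow; exact polygon geometry would differ by a boundary
  band.
* `groupOverlap()` forms the **combined trace** as the union of all
  raters' rasters and reports each rater against it (equivalently
  $100\,|T_r|/|\bigcup T|$, since each raster is a subset of the union).
  The union reading models a combined selection of overlapping traces; an
  intersection reading is available via `combine = "intersection"`.
  Neither is claimed to be the only possible formalization of "percent
  similarity to the combined trace" — both are explicit.
* `summedAreaTable()` sums like-named regions across images per rater
  (missing traces stay missing, not zero), and `krippendorffAlpha()`
  computes interval-level Krippendorff's α = 1 − D_o/D_e on the resulting
  units × raters matrix, with δ(v,v′) = (v−v′)², pairable units being
  those with ≥ 2 ratings. α is undefined (error, not NA) when all pairable
  values coincide. Area measurements are interval data; nominal/ordinal α
  is out of scope. The implementation is verified to 10⁻¹² against an
  independent coincidence-matrix formulation.

## Synthetic data

All tests run without external data, on generators whose ground truth is
exact by construction:

* `synthPlate(n, w, h, seed)` — disjoint jittered-rectangle regions on a
  grid (cells ≥ 10 px);
* `synthBlobImage()` — disks of intensity 255 (no anti-aliasing) on a dim
  noisy background; centers sit ≥ radius inside their region and more than
  one diameter apart, so at zero noise thresholding at [128, 255] recovers
  every object exactly and each centroid equals its seeded center. The
  default background (20) with noise SD 10 leaves the threshold > 10 SDs
  away, so count recovery stays essentially exact under noise — the noisy
  check in the tests guards the pipeline plumbing, not a detection limit;
* `synthFillImage()` — exactly `round(f·A)` random pixels per region, so
  volumetric percent area equals recorded truth to the rounding quantum
  100/A;
* `perturbPolygon()` — smooth low-frequency (3-harmonic Fourier) vertex
  displacement with RMS ≈ the requested magnitude, halved until the
  outline is simple again; used to simulate independent raters.

These fixtures emulate geometry and counting statistics, not histology:
no point-spread function, no intensity gradients, no touching objects, no
anatomically shaped regions. Passing tests therefore establish the
correctness of the measurement machinery, not segmentation performance on
real tissue.

Problem sizes used in the shipped tests and in `scripts/acceptance.R`
(12-region 400×300 plates, 3-image batches, ~200-object scenes, 100-record
codec checks) were chosen as the smallest sizes at which every contract is
exercised away from small-sample degeneracies.

## Numerical choices and degenerate inputs

* Rasterization tie-break: half-open as above; both the implementation and
  its oracle share the convention, so agreement is exact, not approximate.
* Control-point reproduction asserted at 10⁻⁹ px; affine reproduction at
  10⁻⁶ px.
* Minimum region area 4 px²; smaller tracings are degenerate and rejected.
* Self-intersecting polygons are rejected by `validatePlate()`
  (`plateFromLabelImage()` additionally rejects multi-part and holed
  blobs: one polygon per region name in this version).
* `.roi` quantization: round-to-nearest on write; coordinates outside
  int16 raise "coordinate overflow" rather than wrapping. Truth-exact
  pipelines should use integer-vertex plates, since archived plates are
  integer by format.
* Duplicate region names and duplicate control sources are errors, not
  warnings.

## Known limitations

One polygon per region (no multi-part regions); no intensity-based
automatic registration (plate assignment is an explicit input table); no
per-object morphometry; overlap and α come without bootstrap confidence
intervals; PNG input is treated as 8-bit (values rescaled to 0–255).

## A worked example

```{r example, eval = FALSE}
dir <- tempfile()
truth <- writeScaffold(dir, nImages = 3, nRegions = 12,
                       width = 400, height = 300, seed = 5)
cfg <- runConfig(imagesDir = file.path(dir, "images"),
                 atlasManifest = file.path(dir, "manifest.csv"),
                 assignCsv = file.path(dir, "assign.csv"),
                 outDir = file.path(dir, "out"), mode = "counts",
                 threshold = c(128, 255), sizeRange = c(3, Inf))
runPipeline(cfg)
read.csv(file.path(dir, "out", "img01_results.csv"))
```
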