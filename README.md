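# atlasquant

Flexible atlas registration and multi-region quantification for 2-D
biological images.

Histological experiments that map a label of interest (c-Fos⁺ nuclei,
perfused vasculature, amyloid plaques, ...) across many anatomical regions
need each tissue image delineated against a reference atlas. `atlasquant`
implements that workflow as a scriptable R library for analysts who curate
their own atlas plates — named polygon outlines saved as ImageJ ROI-set
archives — rather than being tied to one fixed reference atlas, species,
sectioning plane, or hierarchy level.

What it does:

* **ROI I/O** — a bit-level codec for the ImageJ `.roi` format (polygon and
  freehand records) and ROI-set ZIP archives, the interchange format of
  atlas plates (`decodeRoi`, `encodeRoi`, `readRoiArchive`,
  `writeRoiArchive`).
* **Atlas model** — plates and regions as validated S4 objects; manifests
  for curated atlases (`loadAtlas`); programmatic plate construction from
  label images (`plateFromLabelImage`); packaged 12-region and 63-region
  mouse-brain registries (`regionRegistry`).
* **Registration** — per-image linear rescale
  (x·sₓ, y·s_y with sₓ = W_target/W_ref) followed by an optional
  control-point thin-plate-spline free-form deformation that reproduces
  every control pair exactly (`linearFit`, `freeformWarp`); fitted plates
  are persisted for re-loading and rendered as outline overlays.
* **Segmentation** — closed-interval intensity thresholding, 8-connected
  component size filtering, and validation of externally binarized masks
  (`thresholdMask`, `sizeFilter`, `coerceBinary`).
* **Quantification** — per region: rasterized area A, object count n
  (components whose centroid falls in the region), density d = n/A in
  objects/mm², and label percent area p = 100·L/A (`quantifyImage`,
  `writeResults`).
* **Reliability** — combined-trace percent overlap across raters,
  per-rater summed-area tables, and Krippendorff's interval
  α = 1 − D_o/D_e (`groupOverlap`, `summedAreaTable`,
  `krippendorffAlpha`).
* **Synthetic data** — deterministic generators with exact ground truth
  (`synthPlate`, `synthBlobImage`, `synthFillImage`, `perturbPolygon`,
  `writeScaffold`) so the whole pipeline is testable offline.

A command-line front-end (`inst/cli/atlasquant.R`) wraps the batch
pipeline: `run`, `overlap`, `alpha`, `roi inspect|convert`, `simulate`.

## Worked example

Generate a synthetic 3-image study (12 regions, known object counts),
run the counting pipeline, and compare with truth:

```r
library(atlasquant)

dir <- tempfile()
truth <- writeScaffold(dir, nImages = 3, nRegions = 12,
                       width = 400, height = 300, seed = 5)
cfg <- runConfig(imagesDir = file.path(dir, "images"),
                 atlasManifest = file.path(dir, "manifest.csv"),
                 assignCsv = file.path(dir, "assign.csv"),
                 outDir = file.path(dir, "out"), mode = "counts",
                 threshold = c(128, 255), sizeRange = c(3, Inf))
runPipeline(cfg)
head(read.csv(file.path(dir, "out", "img01_results.csv")), 5)
#>   image region area_px area_um2 count density_per_mm2 percent_area
#> 1 img01    R01    5743       NA     6              NA           NA
#> 2 img01    R02    6342       NA    11              NA           NA
#> 3 img01    R03    5209       NA     2              NA           NA
#> 4 img01    R04    6012       NA     5              NA           NA
#> 5 img01    R05    7286       NA     2              NA           NA
```

Each row is one region of the fitted plate: `area_px` its rasterized
pixel support, `count` the number of thresholded objects whose centroid
lies inside it (here 59 objects in total across the image, matching the
generator's ground truth exactly). `area_um2` and `density_per_mm2` fill
in when a pixel size (`umPerPx`) is supplied; `percent_area` is produced
by the volumetric (densitometry) mode instead of `count`.

## Conventions

Coordinates are ImageJ-style: origin at the image top-left, y downward;
pixel (row r, col c) (0-based) has center (c + 0.5, r + 0.5). Masks are
logical `[height, width]` matrices. A pixel belongs to a region iff its
center is inside the polygon under the even–odd rule. Regions may overlap
or nest; measurements are per-region independent. See the methods
vignette (`vignettes/atlas-registration.Rmd`) for the model, parameter
and tolerance choices, and known limitations.
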