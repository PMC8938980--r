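## Measurement core: per-region area, object counts, density and label
## percent area on the shared pixel lattice.
##
## Object-to-region assignment is by exact object centroid (mean of member
## pixel centers) under the even-odd point-in-polygon test. This guarantees
## each object is counted at most once across a set of disjoint regions and
## is fully deterministic; it can differ at region boundaries from
## clip-based particle analysis, which splits boundary objects.

#' Measure one region against a label mask
#'
#' Region area `A` is the rasterized pixel count ([rasterizePolygon()]),
#' so the percent-area numerator and denominator share one pixel lattice.
#' In `counts` mode, `n` is the number of 8-connected mask components whose
#' centroid lies inside the region polygon, and density `d = n / A` is
#' reported in objects/mm^2 when `umPerPx` is given (otherwise left `NA`,
#' never silently per-pixel). In `volumetric` mode, percent area
#' `p = 100 * L / A` where `L` counts label-positive pixels inside the
#' region raster.
#'
#' @param mask Logical label mask; its dims must equal the fitted plate's.
#' @param region A [Region-class] (fitted coordinates).
#' @param mode `"counts"` or `"volumetric"`.
#' @param umPerPx Optional pixel size in micrometres.
#' @param connectivity Object connectivity for counts mode (default 8).
#' @return One-row `data.frame`: `region`, `area_px`, `area_um2`, `count`,
#'   `density_per_mm2`, `percent_area` (fields not in the chosen mode are
#'   `NA`).
#' @export
measureRegion <- function(mask, region, mode = c("counts", "volumetric"),
                          umPerPx = NULL, connectivity = 8) {
  mode <- match.arg(mode)
  stopifnot(is(region, "Region"), is.matrix(mask))
  h <- nrow(mask); w <- ncol(mask)
  ras <- rasterizePolygon(region@polygon, h, w)
  A <- sum(ras)
  if (A == 0L) stop("region '", region@abbrev, "' has no pixel support")
  areaUm2 <- if (is.null(umPerPx)) NA_real_ else A * umPerPx^2
  n <- NA_integer_; d <- NA_real_; p <- NA_real_
  if (mode == "counts") {
    lab <- labelComponents(mask, connectivity)
    if (max(lab) > 0L) {
      idx <- which(lab > 0L)
      l <- lab[idx]
      cx <- ((idx - 1L) %/% h) + 0.5   # col centers
      cy <- ((idx - 1L) %% h) + 0.5    # row centers
      cenx <- tapply(cx, l, mean); ceny <- tapply(cy, l, mean)
      n <- sum(pointInPolygon(cenx, ceny, region@polygon))
    } else n <- 0L
    if (!is.null(umPerPx)) d <- n / (A * umPerPx^2 / 1e6)  # objects per mm^2
  } else {
    p <- 100 * sum(mask & ras) / A
  }
  data.frame(region = region@abbrev, area_px = A, area_um2 = areaUm2,
             count = as.integer(n), density_per_mm2 = d, percent_area = p,
             stringsAsFactors = FALSE)
}

#' Quantify a whole plate against a label mask
#'
#' One [measureRegion()] row per region, in plate order. Regions are
#' measured independently: where regions overlap or nest, an object or
#' pixel contributes to every region containing it.
#'
#' @param mask Logical label mask; dims must equal the plate's reference
#'   dims.
#' @param plate Fitted [AtlasPlate-class].
#' @param mode `"counts"` or `"volumetric"`.
#' @param umPerPx Optional pixel size in micrometres.
#' @param connectivity Object connectivity for counts mode.
#' @return `data.frame` with one row per region.
#' @export
quantifyImage <- function(mask, plate, mode = c("counts", "volumetric"),
                          umPerPx = NULL, connectivity = 8) {
  mode <- match.arg(mode)
  stopifnot(is(plate, "AtlasPlate"))
  if (nrow(mask) != plate@refHeight || ncol(mask) != plate@refWidth)
    stop("mask dims (", ncol(mask), "x", nrow(mask),
         ") do not match plate dims (", plate@refWidth, "x", plate@refHeight, ")")
  # label once for all regions in counts mode
  if (mode == "counts") {
    lab <- labelComponents(mask, connectivity)
    h <- nrow(mask)
    if (max(lab) > 0L) {
      idx <- which(lab > 0L)
      l <- lab[idx]
      cenx <- tapply(((idx - 1L) %/% h) + 0.5, l, mean)
      ceny <- tapply(((idx - 1L) %% h) + 0.5, l, mean)
    } else cenx <- ceny <- numeric(0)
  }
  rows <- lapply(plate@regions, function(r) {
    ras <- rasterizePolygon(r@polygon, nrow(mask), ncol(mask))
    A <- sum(ras)
    if (A == 0L) stop("region '", r@abbrev, "' has no pixel support")
    areaUm2 <- if (is.null(umPerPx)) NA_real_ else A * umPerPx^2
    n <- NA_integer_; d <- NA_real_; p <- NA_real_
    if (mode == "counts") {
      n <- if (length(cenx)) sum(pointInPolygon(cenx, ceny, r@polygon)) else 0L
      if (!is.null(umPerPx)) d <- n / (A * umPerPx^2 / 1e6)
    } else p <- 100 * sum(mask & ras) / A
    data.frame(region = r@abbrev, area_px = A, area_um2 = areaUm2,
               count = as.integer(n), density_per_mm2 = d, percent_area = p,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Write per-region results as CSV
#'
#' Header `image,region,area_px,area_um2,count,density_per_mm2,percent_area`;
#' fields not produced by the chosen analysis mode are blank. Row order
#' follows the input, so identical inputs produce byte-identical files.
#'
#' @param rows `data.frame` from [quantifyImage()].
#' @param imageId Image identifier written in the `image` column.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
writeResults <- function(rows, imageId, path) {
  if (!NROW(rows)) stop("no result rows to write")
  out <- cbind(data.frame(image = imageId, stringsAsFactors = FALSE), rows)
  tryCatch(
    utils::write.csv(out, path, row.names = FALSE, na = ""),
    error = function(e) stop("failed to write results to '", path, "': ",
                             conditionMessage(e)))
  invisible(path)
}
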