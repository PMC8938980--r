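## Atlas model: load a curated atlas from ROI archives + a manifest CSV,
## build plates programmatically from label images, validate geometry.

# regions smaller than this are treated as degenerate tracings
.minRegionAreaPx <- 4

#' Validate an atlas plate
#'
#' Checks the plate's geometric invariants and returns human-readable
#' violation descriptions instead of raising: unique region abbrevs, simple
#' polygons, area at least 4 px^2, and all vertices inside
#' `[0, refWidth] x [0, refHeight]`.
#'
#' @param plate An [AtlasPlate-class].
#' @return Character vector of violations; empty when the plate is valid.
#' @export
validatePlate <- function(plate) {
  stopifnot(is(plate, "AtlasPlate"))
  out <- character()
  ab <- regionNames(plate)
  dup <- unique(ab[duplicated(ab)])
  if (length(dup)) out <- c(out, paste0(dup, ": duplicate region abbrev"))
  for (r in plate@regions) {
    p <- r@polygon
    if (nrow(p) < 3L) {
      out <- c(out, paste0(r@abbrev, ": fewer than 3 vertices"))
      next
    }
    if (!polygonIsSimple(p)) out <- c(out, paste0(r@abbrev, ": self-intersecting"))
    else if (shoelaceArea(p) < .minRegionAreaPx)
      out <- c(out, paste0(r@abbrev, ": area below minimum (",
                           .minRegionAreaPx, " px^2)"))
    if (any(p[, 1] < 0) || any(p[, 1] > plate@refWidth) ||
        any(p[, 2] < 0) || any(p[, 2] > plate@refHeight))
      out <- c(out, paste0(r@abbrev, ": vertex out of bounds [0,",
                           plate@refWidth, "]x[0,", plate@refHeight, "]"))
  }
  out
}

#' Load an atlas from a manifest
#'
#' The manifest is a CSV with header `plate_id,archive,ref_width,ref_height`
#' (an optional `label` column is carried through as a plate label). Archive
#' paths are resolved relative to the manifest's directory. Each archive is
#' parsed with [readRoiArchive()] and the resulting plate must pass
#' [validatePlate()]. Optional region full names can be supplied as a second
#' CSV `abbrev,full_name` (the packaged registries ship in this form, see
#' [regionRegistry()]).
#'
#' @param manifestPath Path to the manifest CSV.
#' @param name Atlas name (defaults to the manifest file stem).
#' @param orientation Sectioning plane: `"coronal"`, `"sagittal"`,
#'   `"horizontal"` or `"other"`.
#' @param fullNamesPath Optional CSV mapping `abbrev` to `full_name`.
#' @return An [Atlas-class].
#' @export
loadAtlas <- function(manifestPath, name = NULL, orientation = "other",
                      fullNamesPath = NULL) {
  if (!file.exists(manifestPath)) stop("manifest not found: ", manifestPath)
  man <- utils::read.csv(manifestPath, stringsAsFactors = FALSE)
  req <- c("plate_id", "archive", "ref_width", "ref_height")
  if (!all(req %in% names(man)))
    stop("manifest must have columns ", paste(req, collapse = ", "))
  if (anyDuplicated(man$plate_id))
    stop("duplicate plate_id in manifest: ",
         paste(unique(man$plate_id[duplicated(man$plate_id)]), collapse = ", "))
  fullNames <- NULL
  if (!is.null(fullNamesPath)) {
    fn <- utils::read.csv(fullNamesPath, stringsAsFactors = FALSE)
    fullNames <- stats::setNames(fn$full_name, fn$abbrev)
  }
  base <- dirname(manifestPath)
  platesList <- vector("list", nrow(man))
  for (i in seq_len(nrow(man))) {
    arch <- man$archive[i]
    if (!file.exists(arch)) arch <- file.path(base, man$archive[i])
    if (!file.exists(arch))
      stop("archive not found for plate '", man$plate_id[i], "': ", man$archive[i])
    rois <- readRoiArchive(arch)
    regs <- lapply(rois, function(r) {
      fn <- if (!is.null(fullNames) && r@name %in% names(fullNames))
        fullNames[[r@name]] else NA_character_
      Region(r@name, r@coords, fullName = fn)
    })
    plate <- AtlasPlate(man$plate_id[i], man$ref_width[i], man$ref_height[i],
                        unname(regs))
    bad <- validatePlate(plate)
    if (length(bad))
      stop("plate '", man$plate_id[i], "' failed validation: ",
           paste(bad, collapse = "; "))
    platesList[[i]] <- plate
  }
  if (is.null(name)) name <- sub("\\.[^.]*$", "", basename(manifestPath))
  Atlas(name, platesList, orientation = orientation)
}

#' Packaged region registries
#'
#' The two region sets shipped with the package: a lower-level whole-brain
#' mouse registry of 12 major regions (amygdala through thalamus) and a
#' higher-level registry of 63 regions, both keyed by their standard
#' neuroanatomical abbreviations.
#'
#' @param level `"lower"` (12 regions) or `"higher"` (63 regions).
#' @return `data.frame` with columns `abbrev`, `full_name`.
#' @examples
#' nrow(regionRegistry("lower"))
#' @export
regionRegistry <- function(level = c("lower", "higher")) {
  level <- match.arg(level)
  f <- system.file("extdata",
                   if (level == "lower") "regions_lower.csv" else "regions_higher.csv",
                   package = "atlasquant", mustWork = TRUE)
  utils::read.csv(f, stringsAsFactors = FALSE)
}

#' Render a packaged registry as a synthetic atlas
#'
#' Builds a one-plate [Atlas-class] whose regions carry the abbreviations
#' and full names of a packaged registry, with synthetic disjoint polygon
#' geometry from [synthPlate()]. Real plates are user-traced; this gives the
#' registries runnable geometry for pipelines and tests.
#'
#' @param level `"lower"` or `"higher"`; see [regionRegistry()].
#' @param width,height Plate reference dimensions in px.
#' @param seed Integer seed for the synthetic geometry.
#' @return An [Atlas-class] with one plate.
#' @export
registryAtlas <- function(level = c("lower", "higher"),
                          width = 640, height = 480, seed = 1) {
  level <- match.arg(level)
  reg <- regionRegistry(level)
  plate <- synthPlate(nrow(reg), width, height, seed)
  regs <- mapply(function(r, ab, fn) Region(ab, r@polygon, fullName = fn),
                 plate@regions, reg$abbrev, reg$full_name, SIMPLIFY = FALSE)
  Atlas(paste0(level, "-level registry"),
        list(AtlasPlate(paste0(level, "_01"), width, height, regs)),
        orientation = "sagittal")
}

#' Build a plate by tracing a label image
#'
#' Converts an integer-coded label image (0 = background) into an
#' [AtlasPlate-class]: each code's support must be a single 4-connected
#' blob, whose outer boundary is traced along pixel-corner contours
#' (vertices on the pixel-grid corner lattice). With corner-lattice vertices
#' and the pixel-center rasterization rule, [rasterizePolygon()] on the
#' traced polygon recovers the blob exactly for hole-free blobs.
#'
#' @param labels Integer matrix of region codes; 0 is background.
#' @param nameMap Named character vector or list mapping code (as character)
#'   to region abbrev; defaults to `R<code>`.
#' @param plateId Plate id for the result.
#' @return An [AtlasPlate-class] with one region per code, in code order.
#' @export
plateFromLabelImage <- function(labels, nameMap = NULL, plateId = "traced") {
  stopifnot(is.matrix(labels))
  codes <- sort(unique(as.vector(labels)))
  codes <- codes[codes != 0]
  if (!length(codes)) stop("no regions: label image is all background")
  if (!is.null(nameMap)) {
    miss <- setdiff(as.character(codes), names(nameMap))
    if (length(miss)) stop("codes missing from name map: ",
                           paste(miss, collapse = ", "))
  }
  h <- nrow(labels); w <- ncol(labels)
  regs <- vector("list", length(codes))
  for (k in seq_along(codes)) {
    m <- labels == codes[k]
    lab <- labelComponents(m, connectivity = 4)
    ab <- if (is.null(nameMap)) sprintf("R%d", codes[k])
          else as.character(nameMap[[as.character(codes[k])]])
    if (max(lab) != 1L)
      stop("region not simply connected: code ", codes[k], " ('", ab,
           "') has ", max(lab), " 4-connected components")
    if (sum(m) < .minRegionAreaPx)
      stop("region '", ab, "' area below minimum (", .minRegionAreaPx, " px^2)")
    poly <- traceBlobBoundary(m)
    # holes make the traced outline cover more pixels than the blob
    if (sum(rasterizePolygon(poly, h, w)) != sum(m))
      stop("region not simply connected: code ", codes[k], " ('", ab,
           "') contains holes")
    regs[[k]] <- Region(ab, poly)
  }
  plate <- AtlasPlate(plateId, w, h, regs)
  bad <- validatePlate(plate)
  if (length(bad)) stop("traced plate failed validation: ",
                        paste(bad, collapse = "; "))
  plate
}

## Crack-following boundary trace of a single blob.
## Walks the cracks between inside and outside pixels keeping the blob on
## the right-hand side (y down), recording a vertex at every turn; corners
## live on the pixel-corner lattice. Diagonal self-touch configurations are
## resolved by turning right, which keeps the outer loop closed.
traceBlobBoundary <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  inside <- function(r, c) r >= 0L && r < h && c >= 0L && c < w && mask[r + 1L, c + 1L]
  start <- which(t(mask))[1]            # row-major first inside pixel
  r0 <- (start - 1L) %/% w; c0 <- (start - 1L) %% w
  # start on the top edge of that pixel, moving +x, blob on the right
  cx <- c0; cy <- r0
  dx <- 1L; dy <- 0L
  verts <- list()
  startState <- c(cx, cy, dx, dy)
  steps <- 0L
  repeat {
    # pixels ahead of the corner: front-left and front-right of direction d
    # left normal (y down) = (dy, -dx); right normal = (-dy, dx)
    flc <- c(floor(cx + (dx + dy) / 2), floor(cy + (dy - dx) / 2))
    frc <- c(floor(cx + (dx - dy) / 2), floor(cy + (dy + dx) / 2))
    fl <- inside(flc[2], flc[1])
    fr <- inside(frc[2], frc[1])
    if (fr && fl) {        # turn left
      tmp <- dx; dx <- dy; dy <- -tmp
      verts[[length(verts) + 1L]] <- c(cx, cy)
    } else if (!fr) {      # turn right
      tmp <- dx; dx <- -dy; dy <- tmp
      verts[[length(verts) + 1L]] <- c(cx, cy)
    }                      # else straight
    if (steps > 0L && cx == startState[1] && cy == startState[2] &&
        dx == startState[3] && dy == startState[4]) break
    cx <- cx + dx; cy <- cy + dy
    steps <- steps + 1L
    if (steps > 4L * (h * w + 4L))
      stop("boundary trace failed to close")  # defensive; cannot normally trigger
  }
  poly <- do.call(rbind, verts)
  dimnames(poly) <- list(NULL, c("x", "y"))
  storage.mode(poly) <- "double"
  poly
}
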