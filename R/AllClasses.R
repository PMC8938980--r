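#' @import methods
NULL

#' RoiRecord: one named closed polygon outline
#'
#' The in-memory form of a single ImageJ `.roi` record: a named, implicitly
#' closed polygon (or freehand trace) in pixel coordinates. The coordinate
#' origin is the image top-left corner with y increasing downward, matching
#' ImageJ. Vertices are stored as floating point; they are quantized to the
#' nearest integer only when encoded to the int16-based on-disk format.
#'
#' @slot name Region name; nonempty, unique within an archive.
#' @slot kind Either `"polygon"` or `"freehand"` (ImageJ type bytes 0 and 7).
#' @slot coords Numeric matrix with columns `x`, `y`; at least 3 rows. The
#'   polygon is implicitly closed (last vertex connects back to the first).
#'
#' @seealso [decodeRoi()], [encodeRoi()], [readRoiArchive()]
#' @export
setClass("RoiRecord",
  representation(name = "character", kind = "character", coords = "matrix"),
  validity = function(object) {
    msg <- character()
    if (length(object@name) != 1L || is.na(object@name) || !nzchar(object@name))
      msg <- c(msg, "name must be a single nonempty string")
    if (length(object@kind) != 1L || !object@kind %in% c("polygon", "freehand"))
      msg <- c(msg, "kind must be 'polygon' or 'freehand'")
    if (!is.numeric(object@coords) || ncol(object@coords) != 2L)
      msg <- c(msg, "coords must be a 2-column numeric matrix")
    else {
      if (nrow(object@coords) < 3L) msg <- c(msg, "a polygon needs at least 3 vertices")
      if (any(!is.finite(object@coords))) msg <- c(msg, "coords must be finite")
    }
    if (length(msg)) msg else TRUE
  }
)

#' Construct a RoiRecord
#'
#' @param name Region name.
#' @param coords Two-column matrix (or data.frame) of x, y vertices.
#' @param kind `"polygon"` (default) or `"freehand"`.
#' @return A [RoiRecord-class] object.
#' @examples
#' tri <- RoiRecord("tri", rbind(c(0, 0), c(10, 0), c(0, 10)))
#' roiName(tri)
#' @export
RoiRecord <- function(name, coords, kind = "polygon") {
  coords <- as.matrix(coords)
  dimnames(coords) <- list(NULL, c("x", "y"))
  storage.mode(coords) <- "double"
  new("RoiRecord", name = as.character(name), kind = kind, coords = coords)
}

#' Region: a named anatomical region outline
#'
#' A simple (non-self-intersecting) closed polygon with strictly positive
#' area, identified by its atlas abbreviation (e.g. `"HPF"`).
#'
#' @slot abbrev Region abbreviation.
#' @slot fullName Optional full region name (`NA` when unknown).
#' @slot polygon Numeric matrix of x, y vertices in plate pixel coordinates.
#' @export
setClass("Region",
  representation(abbrev = "character", fullName = "character", polygon = "matrix"),
  validity = function(object) {
    msg <- character()
    if (length(object@abbrev) != 1L || is.na(object@abbrev) || !nzchar(object@abbrev))
      msg <- c(msg, "abbrev must be a single nonempty string")
    if (!is.numeric(object@polygon) || ncol(object@polygon) != 2L ||
        nrow(object@polygon) < 3L || any(!is.finite(object@polygon)))
      msg <- c(msg, "polygon must be a finite 2-column matrix with >= 3 vertices")
    if (length(msg)) msg else TRUE
  }
)

#' Construct a Region
#' @param abbrev Region abbreviation, e.g. `"HPF"`.
#' @param polygon Two-column matrix of x, y vertices.
#' @param fullName Optional full name.
#' @return A [Region-class] object.
#' @export
Region <- function(abbrev, polygon, fullName = NA_character_) {
  polygon <- as.matrix(polygon)
  dimnames(polygon) <- list(NULL, c("x", "y"))
  storage.mode(polygon) <- "double"
  new("Region", abbrev = as.character(abbrev),
      fullName = as.character(fullName), polygon = polygon)
}

#' AtlasPlate: an ordered set of named regions on one reference section
#'
#' One 2-D atlas section: an ordered list of [Region-class] outlines drawn
#' against fixed reference dimensions. Regions may overlap or be nested --
#' custom atlas organizations are explicitly allowed -- and every downstream
#' measurement is per-region independent, so an object or pixel inside two
#' overlapping regions contributes to both.
#'
#' @slot plateId Plate identifier, unique within an [Atlas-class].
#' @slot refWidth,refHeight Reference dimensions (px) the polygons were drawn
#'   against.
#' @slot regions Ordered list of [Region-class] objects with unique abbrevs.
#' @export
setClass("AtlasPlate",
  representation(plateId = "character", refWidth = "numeric",
                 refHeight = "numeric", regions = "list"),
  validity = function(object) {
    msg <- character()
    if (length(object@plateId) != 1L || !nzchar(object@plateId))
      msg <- c(msg, "plateId must be a single nonempty string")
    if (length(object@refWidth) != 1L || !is.finite(object@refWidth) || object@refWidth <= 0)
      msg <- c(msg, "refWidth must be a positive number")
    if (length(object@refHeight) != 1L || !is.finite(object@refHeight) || object@refHeight <= 0)
      msg <- c(msg, "refHeight must be a positive number")
    if (!all(vapply(object@regions, is, logical(1), "Region")))
      msg <- c(msg, "regions must all be Region objects")
    else {
      ab <- vapply(object@regions, function(r) r@abbrev, character(1))
      if (anyDuplicated(ab)) msg <- c(msg, "region abbrevs must be unique within a plate")
    }
    if (length(msg)) msg else TRUE
  }
)

#' Construct an AtlasPlate
#' @param plateId Plate identifier.
#' @param refWidth,refHeight Reference dimensions in pixels.
#' @param regions List of [Region-class] objects.
#' @return An [AtlasPlate-class] object.
#' @export
AtlasPlate <- function(plateId, refWidth, refHeight, regions) {
  new("AtlasPlate", plateId = as.character(plateId),
      refWidth = as.numeric(refWidth), refHeight = as.numeric(refHeight),
      regions = regions)
}

#' Atlas: an ordered collection of plates
#'
#' @slot name Atlas name.
#' @slot orientation One of `"coronal"`, `"sagittal"`, `"horizontal"`,
#'   `"other"`.
#' @slot plates Ordered list of [AtlasPlate-class] objects with unique ids.
#' @export
setClass("Atlas",
  representation(name = "character", orientation = "character", plates = "list"),
  validity = function(object) {
    msg <- character()
    if (!object@orientation %in% c("coronal", "sagittal", "horizontal", "other"))
      msg <- c(msg, "orientation must be coronal, sagittal, horizontal or other")
    if (length(object@plates) < 1L)
      msg <- c(msg, "an atlas needs at least one plate")
    else if (!all(vapply(object@plates, is, logical(1), "AtlasPlate")))
      msg <- c(msg, "plates must all be AtlasPlate objects")
    else {
      ids <- vapply(object@plates, function(p) p@plateId, character(1))
      if (anyDuplicated(ids)) msg <- c(msg, "plate ids must be unique")
    }
    if (length(msg)) msg else TRUE
  }
)

#' Construct an Atlas
#' @param name Atlas name.
#' @param plates List of [AtlasPlate-class] objects.
#' @param orientation Sectioning plane of the plates.
#' @return An [Atlas-class] object.
#' @export
Atlas <- function(name, plates, orientation = "other") {
  new("Atlas", name = as.character(name), orientation = orientation,
      plates = plates)
}

#' ReliabilityResult: Krippendorff's alpha with its components
#'
#' Holds the chance-corrected interrater agreement coefficient
#' alpha = 1 - Do/De, together with the observed disagreement Do, the
#' expected-by-chance disagreement De, and the number of pairable values
#' (values in units rated by at least two raters).
#'
#' @slot alpha The agreement coefficient; 1 is perfect reliability.
#' @slot Do Observed disagreement.
#' @slot De Expected disagreement.
#' @slot nPairable Number of pairable values.
#' @export
setClass("ReliabilityResult",
  representation(alpha = "numeric", Do = "numeric", De = "numeric",
                 nPairable = "integer"),
  validity = function(object) {
    if (object@De > 0 && abs(object@alpha - (1 - object@Do / object@De)) > 1e-8)
      "alpha must equal 1 - Do/De" else TRUE
  }
)

## ---- accessors ----

#' @describeIn RoiRecord-class Region name stored in the record.
#' @param object A RoiRecord.
#' @export
roiName <- function(object) object@name
#' @describeIn RoiRecord-class `"polygon"` or `"freehand"`.
#' @export
roiKind <- function(object) object@kind
#' @describeIn RoiRecord-class Vertex matrix (columns x, y).
#' @export
roiCoords <- function(object) object@coords

#' @describeIn AtlasPlate-class Plate identifier.
#' @param object An AtlasPlate.
#' @export
plateId <- function(object) object@plateId
#' @describeIn AtlasPlate-class Reference width in px.
#' @export
refWidth <- function(object) object@refWidth
#' @describeIn AtlasPlate-class Reference height in px.
#' @export
refHeight <- function(object) object@refHeight
#' @describeIn AtlasPlate-class Ordered list of regions.
#' @export
regions <- function(object) object@regions
#' @describeIn AtlasPlate-class Region abbreviations, in plate order.
#' @export
regionNames <- function(object) vapply(object@regions, function(r) r@abbrev, character(1))

#' @describeIn Atlas-class Ordered list of plates.
#' @param object An Atlas.
#' @export
plates <- function(object) object@plates
#' @describeIn Atlas-class Fetch one plate by id.
#' @param id Plate id.
#' @export
getPlate <- function(object, id) {
  ids <- vapply(object@plates, function(p) p@plateId, character(1))
  i <- match(id, ids)
  if (is.na(i)) stop("no plate with id '", id, "'")
  object@plates[[i]]
}

#' @describeIn ReliabilityResult-class The alpha coefficient.
#' @param object A ReliabilityResult.
#' @export
alphaValue <- function(object) object@alpha
#' @describeIn ReliabilityResult-class Observed disagreement.
#' @export
observedDisagreement <- function(object) object@Do
#' @describeIn ReliabilityResult-class Expected disagreement.
#' @export
expectedDisagreement <- function(object) object@De
#' @describeIn ReliabilityResult-class Number of pairable values.
#' @export
nPairable <- function(object) object@nPairable

## ---- show methods ----

setMethod("show", "RoiRecord", function(object) {
  cat("RoiRecord '", object@name, "' (", object@kind, "), ",
      nrow(object@coords), " vertices\n", sep = "")
})

setMethod("show", "Region", function(object) {
  cat("Region ", object@abbrev,
      if (!is.na(object@fullName)) paste0(" (", object@fullName, ")"),
      ": ", nrow(object@polygon), " vertices, area ",
      signif(shoelaceArea(object@polygon), 6), " px^2\n", sep = "")
})

setMethod("show", "AtlasPlate", function(object) {
  cat("AtlasPlate '", object@plateId, "': ", length(object@regions),
      " regions on ", object@refWidth, "x", object@refHeight, " px\n", sep = "")
  ab <- regionNames(object)
  cat("  regions: ", paste(utils::head(ab, 12), collapse = ", "),
      if (length(ab) > 12) ", ...", "\n", sep = "")
})

setMethod("show", "Atlas", function(object) {
  cat("Atlas '", object@name, "' (", object@orientation, "): ",
      length(object@plates), " plate(s), ",
      sum(vapply(object@plates, function(p) length(p@regions), integer(1))),
      " regions total\n", sep = "")
})

setMethod("show", "ReliabilityResult", function(object) {
  cat("Krippendorff's alpha (interval): ", format(object@alpha, digits = 6),
      "\n  Do = ", format(object@Do, digits = 6),
      ", De = ", format(object@De, digits = 6),
      ", pairable values = ", object@nPairable, "\n", sep = "")
})
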