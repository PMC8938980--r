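## Plate-to-image registration: global linear rescale, then control-point
## thin-plate-spline free-form deformation acting on polygon vertices.
## The deformation is an explicit, documented surrogate for interactive
## free-form adjustment: a smooth displacement field that reproduces every
## control pair exactly.

#' Linearly fit a plate to target image dimensions
#'
#' Scales every region vertex by `sx = targetWidth / refWidth` and
#' `sy = targetHeight / refHeight`; the fitted plate's reference dimensions
#' become the target dimensions. Region order and names are preserved, and
#' polygon (shoelace) areas scale by exactly `sx * sy`.
#'
#' @param plate An [AtlasPlate-class].
#' @param targetWidth,targetHeight Target image dimensions in px.
#' @return List with elements `plate` (the fitted [AtlasPlate-class]) and
#'   `fit` (list with `sx`, `sy`).
#' @export
linearFit <- function(plate, targetWidth, targetHeight) {
  stopifnot(is(plate, "AtlasPlate"))
  if (targetWidth <= 0 || targetHeight <= 0)
    stop("target dimensions must be positive")
  sx <- targetWidth / refWidth(plate)
  sy <- targetHeight / refHeight(plate)
  regs <- lapply(plate@regions, function(r) {
    p <- r@polygon
    p[, 1] <- p[, 1] * sx
    p[, 2] <- p[, 2] * sy
    Region(r@abbrev, p, fullName = r@fullName)
  })
  list(plate = AtlasPlate(plate@plateId, targetWidth, targetHeight, regs),
       fit = list(sx = sx, sy = sy))
}

## Solve the thin-plate-spline displacement interpolant.
## src, dst: k x 2 matrices. Returns a function mapping an n x 2 matrix of
## points to their warped positions. Kernel U(r) = r^2 log r; the affine
## term makes the interpolant reproduce exactly-affine pair sets everywhere.
tpsSolve <- function(src, dst) {
  k <- nrow(src)
  if (anyDuplicated(src) > 0)
    stop("duplicate control source points")
  if (k == 1L) {
    shift <- dst[1, ] - src[1, ]
    return(function(p) sweep(p, 2, -shift))
  }
  if (k == 2L) {
    # unique similarity transform (rotation + isotropic scale + translation)
    # through both pairs: a zero-bending interpolant, exact in closed form
    zs <- complex(real = src[, 1], imaginary = src[, 2])
    zd <- complex(real = dst[, 1], imaginary = dst[, 2])
    a <- (zd[2] - zd[1]) / (zs[2] - zs[1])
    b <- zd[1] - a * zs[1]
    return(function(p) {
      z <- a * complex(real = p[, 1], imaginary = p[, 2]) + b
      cbind(Re(z), Im(z))
    })
  }
  U <- function(r2) ifelse(r2 == 0, 0, 0.5 * r2 * log(r2))  # r^2 log r
  d2 <- as.matrix(stats::dist(src))^2
  K <- U(d2)
  P <- cbind(1, src)
  if (qr(P)$rank < 3L)
    stop("degenerate control configuration: source points are collinear")
  M <- rbind(cbind(K, P), cbind(t(P), matrix(0, 3, 3)))
  rhs <- rbind(dst, matrix(0, 3, 2))
  coef <- solve(M, rhs)
  wts <- coef[seq_len(k), , drop = FALSE]
  aff <- coef[k + 1:3, , drop = FALSE]
  function(p) {
    p <- as.matrix(p)
    d2p <- outer(p[, 1], src[, 1], "-")^2 + outer(p[, 2], src[, 2], "-")^2
    cbind(1, p) %*% aff + U(d2p) %*% wts
  }
}

#' Free-form warp of a plate via control points
#'
#' Applies a smooth displacement field `W` with `W(src_k) = dst_k` exactly
#' to every region vertex. Zero pairs is the identity; one pair a global
#' translation; two pairs the unique similarity transform (rotation,
#' isotropic scale, translation) through both pairs, a zero-bending member
#' of the same family; three or more non-collinear pairs a thin-plate
#' radial-basis displacement interpolation with affine term, so
#' exactly-affine pair sets reproduce the affine map at every point. The
#' warp acts on vertices only (regions are deformed, the image is never
#' resampled); densify dense outlines with [densifyPolygon()] before strong
#' warps.
#'
#' @param plate An [AtlasPlate-class].
#' @param pairs Control pairs: a data.frame/matrix with columns
#'   `src_x,src_y,dst_x,dst_y`, or `NULL`/0-row for identity.
#' @param perRegion When `TRUE`, named list `pairs` per region abbrev is
#'   applied independently per region (faithful to fully independent manual
#'   adjustment); default is one global plate warp, which keeps shared
#'   boundaries coherent.
#' @return The warped [AtlasPlate-class].
#' @export
freeformWarp <- function(plate, pairs, perRegion = FALSE) {
  stopifnot(is(plate, "AtlasPlate"))
  if (perRegion) {
    stopifnot(is.list(pairs))
    regs <- lapply(plate@regions, function(r) {
      pr <- pairs[[r@abbrev]]
      if (is.null(pr) || NROW(pr) == 0L) return(r)
      warp <- tpsSolve(asControlMatrix(pr)[, 1:2, drop = FALSE],
                       asControlMatrix(pr)[, 3:4, drop = FALSE])
      Region(r@abbrev, warp(r@polygon), fullName = r@fullName)
    })
    return(AtlasPlate(plate@plateId, plate@refWidth, plate@refHeight, regs))
  }
  if (is.null(pairs) || NROW(pairs) == 0L) return(plate)
  cm <- asControlMatrix(pairs)
  warp <- tpsSolve(cm[, 1:2, drop = FALSE], cm[, 3:4, drop = FALSE])
  regs <- lapply(plate@regions, function(r)
    Region(r@abbrev, warp(r@polygon), fullName = r@fullName))
  AtlasPlate(plate@plateId, plate@refWidth, plate@refHeight, regs)
}

asControlMatrix <- function(pairs) {
  m <- as.matrix(as.data.frame(pairs))
  if (ncol(m) != 4L) stop("control pairs need 4 columns: src_x,src_y,dst_x,dst_y")
  storage.mode(m) <- "double"
  if (any(!is.finite(m))) stop("control pair coordinates must be finite")
  m
}

#' Export a fitted plate for later re-loading
#'
#' Persists the fitted registration of one image as an ROI-set ZIP archive
#' named `<imageId>.zip` in `outDir`, and appends a line
#' (image id, plate id, dims) to the run log `fitted_plates_log.csv` there.
#' Plates failing [validatePlate()] are refused with the violation list.
#' Reading the archive back reproduces the fitted polygons up to integer
#' quantization.
#'
#' @param plate Fitted [AtlasPlate-class].
#' @param imageId Image identifier (archive stem).
#' @param outDir Output directory (created if missing).
#' @return Path of the written archive, invisibly.
#' @export
exportFittedPlate <- function(plate, imageId, outDir) {
  bad <- validatePlate(plate)
  if (length(bad))
    stop("refusing to export invalid plate: ", paste(bad, collapse = "; "))
  if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)
  rois <- lapply(plate@regions, function(r) RoiRecord(r@abbrev, r@polygon))
  path <- file.path(outDir, paste0(imageId, ".zip"))
  writeRoiArchive(rois, path)
  logPath <- file.path(outDir, "fitted_plates_log.csv")
  line <- data.frame(image_id = imageId, plate_id = plate@plateId,
                     width = plate@refWidth, height = plate@refHeight)
  utils::write.table(line, logPath, sep = ",", row.names = FALSE,
                     col.names = !file.exists(logPath), append = file.exists(logPath))
  invisible(path)
}

#' Render region outlines over an image
#'
#' Returns an RGB copy of the grayscale image with 1-px region outlines
#' burned in (outline = rasterized region pixels with at least one
#' 4-neighbor outside the raster). With `labels = TRUE` the region abbrevs
#' are additionally burned in with a small bitmap font at each polygon
#' centroid. The input is untouched.
#'
#' @param image Numeric matrix; plate reference dims must equal `dim(image)`
#'   (height, width).
#' @param plate An [AtlasPlate-class] fitted to this image.
#' @param color Length-3 RGB in [0,1] for outlines and labels.
#' @param labels Burn region-name labels (default `FALSE`).
#' @return Numeric array `[height, width, 3]` with values in [0,1].
#' @export
renderOverlay <- function(image, plate, color = c(1, 0, 0), labels = FALSE) {
  stopifnot(is.matrix(image), is(plate, "AtlasPlate"))
  h <- nrow(image); w <- ncol(image)
  if (h != plate@refHeight || w != plate@refWidth)
    stop("plate reference dims (", plate@refWidth, "x", plate@refHeight,
         ") do not match image dims (", w, "x", h, ")")
  g <- image
  if (max(g) > 1) g <- g / max(g)
  rgb <- array(g, dim = c(h, w, 3))
  for (r in plate@regions) {
    ras <- rasterizePolygon(r@polygon, h, w)
    edge <- outlinePixels(ras)
    for (ch in 1:3) {
      plane <- rgb[, , ch]
      plane[edge] <- color[ch]
      rgb[, , ch] <- plane
    }
    if (labels) rgb <- burnText(rgb, r@abbrev, polygonCentroid(r@polygon), color)
  }
  rgb
}

## pixels of a raster with a 4-neighbor outside the raster (or on the border)
outlinePixels <- function(ras) {
  h <- nrow(ras); w <- ncol(ras)
  pad <- matrix(FALSE, h + 2, w + 2)
  pad[2:(h + 1), 2:(w + 1)] <- ras
  interior <- pad[1:h, 2:(w + 1)] & pad[3:(h + 2), 2:(w + 1)] &
              pad[2:(h + 1), 1:w] & pad[2:(h + 1), 3:(w + 2)]
  ras & !interior
}
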