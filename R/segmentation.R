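## Label segmentation: intensity-range thresholding, connected-component
## size filtering, and validation of externally binarized masks.

#' Threshold an image into a label mask
#'
#' A pixel is label-positive exactly when `lo <= value <= hi` (closed
#' interval, matching ImageJ threshold semantics). Intensities are compared
#' in the image's native scale; no normalization is applied.
#'
#' @param image 2-D numeric matrix.
#' @param lo,hi Intensity bounds, `lo <= hi`.
#' @return Logical mask matrix of the same dimensions.
#' @export
thresholdMask <- function(image, lo, hi) {
  if (!is.matrix(image) || !is.numeric(image))
    stop("image must be a 2-D numeric matrix")
  if (lo > hi) stop("lo must not exceed hi")
  image >= lo & image <= hi
}

#' Label connected components of a mask
#'
#' Frontier-based flood fill over foreground pixels. Connectivity 8
#' (diagonal neighbors connect, the ImageJ particle-analysis default) or 4.
#' Components are numbered 1..k in raster order of their first pixel.
#'
#' @param mask Logical matrix.
#' @param connectivity 8 (default) or 4.
#' @return Integer matrix of component labels, 0 = background.
#' @export
labelComponents <- function(mask, connectivity = 8) {
  stopifnot(is.matrix(mask), connectivity %in% c(4, 8))
  h <- nrow(mask); w <- ncol(mask)
  lab <- matrix(0L, h, w)
  offs <- if (connectivity == 8) c(-1L, 1L, -h, h, -h - 1L, -h + 1L, h - 1L, h + 1L)
          else c(-1L, 1L, -h, h)
  # visit seeds in row-major order so labels are deterministic raster order
  fg <- which(t(mask))
  fg <- ((fg - 1L) %% w) * h + ((fg - 1L) %/% w) + 1L  # row-major -> col-major index
  nmax <- h * w
  k <- 0L
  for (seed in fg) {
    if (lab[seed] != 0L) next
    k <- k + 1L
    lab[seed] <- k
    frontier <- seed
    while (length(frontier)) {
      cand <- rep(frontier, each = length(offs)) + offs
      fromRow <- rep((frontier - 1L) %% h, each = length(offs))
      ok <- cand >= 1L & cand <= nmax
      cand <- cand[ok]; fromRow <- fromRow[ok]
      ok <- abs(((cand - 1L) %% h) - fromRow) <= 1L  # no column wrap-around
      cand <- cand[ok]
      cand <- unique(cand[mask[cand] & lab[cand] == 0L])
      lab[cand] <- k
      frontier <- cand
    }
  }
  lab
}

#' Filter mask objects by size
#'
#' Retains connected components whose pixel count lies in
#' `[minObjPx, maxObjPx]`; all other components are erased. The size filter
#' runs globally, before any regional quantification.
#'
#' @param mask Logical matrix.
#' @param minObjPx,maxObjPx Inclusive size bounds in px^2; `maxObjPx` may be
#'   `Inf`.
#' @param connectivity Component connectivity, 8 (default) or 4.
#' @return Filtered logical mask.
#' @export
sizeFilter <- function(mask, minObjPx = 1, maxObjPx = Inf, connectivity = 8) {
  if (minObjPx > maxObjPx) stop("minObjPx must not exceed maxObjPx")
  if (minObjPx <= 0) stop("minObjPx must be positive")
  lab <- labelComponents(mask, connectivity)
  if (max(lab) == 0L) return(mask & FALSE)
  sizes <- tabulate(lab[lab > 0L])
  keep <- which(sizes >= minObjPx & sizes <= maxObjPx)
  lab > 0L & lab %in% keep
}

#' Coerce a two-valued image to a label mask
#'
#' For images binarized upstream (e.g. by a machine-learning segmentation
#' tool): the lower of the two values maps to background, the higher to
#' label-positive, whatever the values are ({0,255}, {0,1}, ...). A
#' single-valued image yields an all-false mask with a warning; more than
#' two distinct values is an error.
#'
#' @param image 2-D numeric matrix with at most two distinct values.
#' @return Logical mask.
#' @export
coerceBinary <- function(image) {
  if (!is.matrix(image) || !is.numeric(image))
    stop("image must be a 2-D numeric matrix")
  vals <- sort(unique(as.vector(image)))
  if (length(vals) > 2L)
    stop("not a binary image: ", length(vals), " distinct values")
  if (length(vals) == 1L) {
    warning("single-valued image: returning an all-false mask")
    return(image != image[1])
  }
  image == vals[2]
}

#' Read a grayscale image
#'
#' Reads single-channel TIFF or PNG by file extension. TIFFs are read at
#' native integer scale; PNGs (which decode to [0,1]) are rescaled to 0-255.
#' Multi-channel images are reduced to their first channel.
#'
#' @param path Image path (.tif/.tiff/.png).
#' @return Numeric matrix.
#' @export
readImageGray <- function(path) {
  if (!file.exists(path)) stop("image not found: ", path)
  ext <- tolower(sub(".*\\.", "", path))
  img <- switch(ext,
    tif = , tiff = tiff::readTIFF(path, as.is = TRUE),
    png = png::readPNG(path) * 255,
    stop("unsupported image format: .", ext))
  if (length(dim(img)) == 3L) img <- img[, , 1]
  img
}

#' Write a label mask as an 8-bit image
#'
#' Mask true pixels are written as 255, false as 0, as 8-bit TIFF or PNG by
#' extension.
#'
#' @param mask Logical matrix.
#' @param path Output path (.tif/.tiff/.png).
#' @return `path`, invisibly.
#' @export
writeMask <- function(mask, path) {
  img <- matrix(as.numeric(mask), nrow(mask), ncol(mask))
  ext <- tolower(sub(".*\\.", "", path))
  switch(ext,
    tif = , tiff = tiff::writeTIFF(img, path, bits.per.sample = 8L),
    png = png::writePNG(img, path),
    stop("unsupported image format: .", ext))
  invisible(path)
}
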