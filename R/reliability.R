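## Interrater agreement procedures: pairwise and combined-trace percent
## overlap, per-rater summed-area tables, and Krippendorff's interval alpha.
## Overlap is computed on the pixel lattice (rasterized traces at the image
## dimensions), matching a raster-based measurement workflow, not on exact
## polygon geometry.

#' Percent overlap of one trace against a reference
#'
#' `100 * |raster(trace) AND raster(reference)| / |raster(reference)|` --
#' an asymmetric containment measure: 100 means the trace covers the whole
#' reference. For a symmetric index use `dice = TRUE`, which returns
#' `100 * 2|A AND B| / (|A| + |B|)`.
#'
#' @param trace,reference Two-column polygon vertex matrices (or
#'   [Region-class] objects).
#' @param dims Image dimensions `c(height, width)` defining the lattice.
#' @param dice Use the symmetric Dice coefficient instead.
#' @return Percent in [0, 100].
#' @export
percentOverlap <- function(trace, reference, dims, dice = FALSE) {
  a <- rasterizePolygon(asPolygon(trace), dims[1], dims[2])
  b <- rasterizePolygon(asPolygon(reference), dims[1], dims[2])
  nb <- sum(b)
  if (nb == 0L) stop("empty reference raster")
  if (dice) return(100 * 2 * sum(a & b) / (sum(a) + nb))
  100 * sum(a & b) / nb
}

asPolygon <- function(x) {
  if (is(x, "Region")) x@polygon
  else if (is(x, "RoiRecord")) x@coords
  else as.matrix(x)
}

#' Combined-trace group overlap for one region
#'
#' Combines all raters' traces of the same region into one reference and
#' reports each rater's percent similarity to it. With the default
#' `combine = "union"` (a combined selection of all overlapping traces) the
#' value for rater r reduces to `100 * |raster_r| / |union|`, since each
#' individual raster is a subset of the union. `combine = "intersection"`
#' uses the common core as the reference instead.
#'
#' @param traces Named list (rater -> polygon matrix or [Region-class]),
#'   length >= 2.
#' @param dims Image dimensions `c(height, width)`.
#' @param combine `"union"` (default) or `"intersection"`.
#' @return Named numeric vector of percents, one per rater.
#' @export
groupOverlap <- function(traces, dims, combine = c("union", "intersection")) {
  combine <- match.arg(combine)
  if (length(traces) < 2L) stop("group overlap needs at least 2 raters")
  rasters <- lapply(traces, function(t)
    rasterizePolygon(asPolygon(t), dims[1], dims[2]))
  comb <- Reduce(if (combine == "union") `|` else `&`, rasters)
  if (sum(comb) == 0L) stop("empty combined trace")
  out <- vapply(rasters, function(r) 100 * sum(r & comb) / sum(comb), numeric(1))
  names(out) <- names(traces)
  out
}

#' Per-rater summed-area table
#'
#' Rasterized trace areas summed over images for like-named regions, one
#' row per rater and one column per region: the unit table fed to
#' [krippendorffAlpha()]. A region a rater never traced is `NA` (missing),
#' not zero.
#'
#' @param traces `data.frame` with columns `image`, `rater`, `region` and a
#'   list-column `polygon` of vertex matrices.
#' @param dims Either `c(height, width)` for all images, or a named list
#'   image -> `c(height, width)`.
#' @param umPerPx Optional micrometres per pixel; areas are then um^2.
#' @return Numeric matrix raters x regions (dimnames set), `NA` for missing.
#' @export
summedAreaTable <- function(traces, dims, umPerPx = NULL) {
  stopifnot(all(c("image", "rater", "region", "polygon") %in% names(traces)))
  raters <- unique(traces$rater)
  regs <- unique(traces$region)
  tab <- matrix(NA_real_, length(raters), length(regs),
                dimnames = list(raters, regs))
  for (i in seq_len(nrow(traces))) {
    d <- if (is.list(dims) && !is.null(names(dims))) dims[[traces$image[i]]] else dims
    a <- sum(rasterizePolygon(asPolygon(traces$polygon[[i]]), d[1], d[2]))
    if (!is.null(umPerPx)) a <- a * umPerPx^2
    r <- as.character(traces$rater[i]); g <- as.character(traces$region[i])
    tab[r, g] <- if (is.na(tab[r, g])) a else tab[r, g] + a
  }
  tab
}

#' Krippendorff's alpha for interval data
#'
#' Chance-corrected interrater reliability `alpha = 1 - Do/De` with the
#' interval difference function `delta(v, v') = (v - v')^2`. Units are rows
#' (e.g. regions), raters columns; `NA` marks missing ratings. Only units
#' with at least two ratings are pairable. Observed disagreement averages
#' within-unit ordered-pair differences weighted by `1/(m_u - 1)`; expected
#' disagreement averages ordered-pair differences across all pairable
#' values. Values closest to 1 indicate the most reliable measurements.
#'
#' @param values Numeric matrix units x raters, `NA` for missing.
#' @return A [ReliabilityResult-class] holding alpha, Do, De and the number
#'   of pairable values.
#' @examples
#' m <- rbind(c(1, 1), c(2, 2), c(3, 3))
#' alphaValue(krippendorffAlpha(m))
#' @export
krippendorffAlpha <- function(values) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  m_u <- rowSums(!is.na(values))
  pairable <- m_u >= 2L
  if (!any(pairable)) stop("no unit with at least 2 ratings")
  vals <- values[pairable, , drop = FALSE]
  m_u <- m_u[pairable]
  n <- sum(m_u)
  # observed: within-unit ordered pairs, each unit weighted by 1/(m_u - 1)
  Do <- 0
  for (u in seq_len(nrow(vals))) {
    x <- vals[u, !is.na(vals[u, ])]
    Do <- Do + sum(outer(x, x, function(a, b) (a - b)^2)) / (length(x) - 1L)
  }
  Do <- Do / n
  # expected: ordered pairs over all pairable values
  allv <- vals[!is.na(vals)]
  De <- (sum(outer(allv, allv, function(a, b) (a - b)^2))) / (n * (n - 1L))
  if (De == 0) stop("alpha undefined: no expected disagreement")
  new("ReliabilityResult", alpha = 1 - Do / De, Do = Do, De = De,
      nPairable = as.integer(n))
}
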