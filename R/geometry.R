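## Polygon geometry primitives shared by the atlas, registration and
## quantification layers. Conventions used throughout the package:
##  - polygons are n x 2 matrices with columns x, y; origin at the image
##    top-left, y increasing downward (ImageJ convention);
##  - masks are logical matrices [height, width]; pixel (row r, col c) with
##    0-based r, c has center (c + 0.5, r + 0.5);
##  - point-in-polygon uses the even-odd (crossing-number) rule with a
##    half-open tie-break: an edge crossing counts when the ray from the
##    point toward +x strictly precedes the intersection.

#' Shoelace area of a polygon
#'
#' @param polygon Two-column matrix of x, y vertices (implicitly closed).
#' @return Absolute enclosed area in squared coordinate units.
#' @export
shoelaceArea <- function(polygon) {
  x <- polygon[, 1]; y <- polygon[, 2]
  x2 <- c(x[-1], x[1]); y2 <- c(y[-1], y[1])
  abs(sum(x * y2 - x2 * y)) / 2
}

#' Even-odd point-in-polygon test
#'
#' Vectorized crossing-number test. A point lies inside when a ray toward +x
#' crosses the boundary an odd number of times; vertical tie-breaks are
#' half-open (`y1 > py` xor `y2 > py`) and horizontal ones strict
#' (`px < x-intersection`), so points on the left/top boundary count as
#' inside and points on the right/bottom boundary as outside.
#'
#' @param px,py Numeric vectors of point coordinates (recycled together).
#' @param polygon Two-column vertex matrix.
#' @return Logical vector, `TRUE` for inside.
#' @export
pointInPolygon <- function(px, py, polygon) {
  x1 <- polygon[, 1]; y1 <- polygon[, 2]
  x2 <- c(x1[-1], x1[1]); y2 <- c(y1[-1], y1[1])
  inside <- logical(length(px))
  cross <- integer(length(px))
  for (i in seq_along(x1)) {
    if (y1[i] == y2[i]) next
    hit <- (y1[i] > py) != (y2[i] > py)
    if (any(hit)) {
      xint <- x1[i] + (py[hit] - y1[i]) * (x2[i] - x1[i]) / (y2[i] - y1[i])
      cross[hit] <- cross[hit] + (px[hit] < xint)
    }
  }
  cross %% 2L == 1L
}

#' Rasterize a polygon onto a pixel grid
#'
#' A pixel (row r, col c; 0-based) is set when its center
#' (c + 0.5, r + 0.5) lies inside the polygon under the even-odd rule;
#' pixels outside the image are clipped. Implemented as a per-row scanline
#' fill (sorted edge intersections, fill between pairs), which matches the
#' per-pixel crossing-number test exactly under the shared tie-break.
#'
#' @param polygon Two-column vertex matrix.
#' @param height,width Output grid size in pixels.
#' @return Logical matrix `[height, width]`.
#' @export
rasterizePolygon <- function(polygon, height, width) {
  if (!is.matrix(polygon) || nrow(polygon) < 3L)
    stop("degenerate polygon: need at least 3 vertices")
  if (height <= 0 || width <= 0) stop("grid dimensions must be positive")
  mask <- matrix(FALSE, height, width)
  x1 <- polygon[, 1]; y1 <- polygon[, 2]
  x2 <- c(x1[-1], x1[1]); y2 <- c(y1[-1], y1[1])
  keep <- y1 != y2
  if (!any(keep)) return(mask)
  x1 <- x1[keep]; y1k <- y1[keep]; x2 <- x2[keep]; y2k <- y2[keep]
  rlo <- max(0L, as.integer(floor(min(y1k, y2k) - 0.5)))
  rhi <- min(height - 1L, as.integer(ceiling(max(y1k, y2k))))
  if (rhi < rlo) return(mask)
  for (r in rlo:rhi) {
    py <- r + 0.5
    hit <- (y1k > py) != (y2k > py)
    if (!any(hit)) next
    xs <- sort(x1[hit] + (py - y1k[hit]) * (x2[hit] - x1[hit]) / (y2k[hit] - y1k[hit]))
    for (k in seq(1L, length(xs) - 1L, by = 2L)) {
      # fill centers px with xs[k] <= px < xs[k+1]
      c0 <- max(0L, as.integer(ceiling(xs[k] - 0.5)))
      c1 <- min(width - 1L, as.integer(ceiling(xs[k + 1L] - 0.5)) - 1L)
      if (c1 >= c0) mask[r + 1L, (c0 + 1L):(c1 + 1L)] <- TRUE
    }
  }
  mask
}

#' Test whether a polygon is simple
#'
#' Checks every pair of non-adjacent edges for intersection (proper crossings
#' and touches alike) and flags zero-length edges. Adjacent edges sharing one
#' endpoint are allowed.
#'
#' @param polygon Two-column vertex matrix.
#' @return `TRUE` when the polygon is simple.
#' @export
polygonIsSimple <- function(polygon) {
  n <- nrow(polygon)
  if (n < 3L) return(FALSE)
  x1 <- polygon[, 1]; y1 <- polygon[, 2]
  x2 <- c(x1[-1], x1[1]); y2 <- c(y1[-1], y1[1])
  if (any(x1 == x2 & y1 == y2)) return(FALSE)  # zero-length edge
  cross2 <- function(ax, ay, bx, by) ax * by - ay * bx
  for (i in seq_len(n - 2L)) {
    # candidate edges j > i, not adjacent to i
    j <- (i + 2L):n
    if (i == 1L) j <- j[j != n]
    if (!length(j)) next
    d1x <- x2[i] - x1[i]; d1y <- y2[i] - y1[i]
    o1 <- cross2(d1x, d1y, x1[j] - x1[i], y1[j] - y1[i])
    o2 <- cross2(d1x, d1y, x2[j] - x1[i], y2[j] - y1[i])
    d2x <- x2[j] - x1[j]; d2y <- y2[j] - y1[j]
    o3 <- cross2(d2x, d2y, x1[i] - x1[j], y1[i] - y1[j])
    o4 <- cross2(d2x, d2y, x2[i] - x1[j], y2[i] - y1[j])
    proper <- (sign(o1) * sign(o2) < 0) & (sign(o3) * sign(o4) < 0)
    if (any(proper)) return(FALSE)
    # collinear touches / overlaps
    touch <- (o1 == 0 & o2 == 0)
    if (any(touch)) {
      jt <- j[touch]
      for (k in jt) {
        if (max(min(x1[i], x2[i]), min(x1[k], x2[k])) <=
            min(max(x1[i], x2[i]), max(x1[k], x2[k])) &&
            max(min(y1[i], y2[i]), min(y1[k], y2[k])) <=
            min(max(y1[i], y2[i]), max(y1[k], y2[k])))
          return(FALSE)
      }
    }
    # endpoint-on-edge touches
    improper <- !proper & ((o1 == 0 | o2 == 0) & (sign(o3) * sign(o4) <= 0) |
                           (o3 == 0 | o4 == 0) & (sign(o1) * sign(o2) <= 0))
    if (any(improper & !touch)) return(FALSE)
  }
  TRUE
}

#' Densify polygon edges
#'
#' Inserts evenly spaced vertices so that no edge exceeds `maxEdgePx`.
#' Useful before strong free-form warps, which act on vertices only.
#'
#' @param polygon Two-column vertex matrix.
#' @param maxEdgePx Maximum allowed edge length in px.
#' @return Vertex matrix with the same shape, possibly more rows.
#' @export
densifyPolygon <- function(polygon, maxEdgePx) {
  stopifnot(maxEdgePx > 0)
  n <- nrow(polygon)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    a <- polygon[i, ]; b <- polygon[if (i == n) 1L else i + 1L, ]
    len <- sqrt(sum((b - a)^2))
    k <- max(1L, ceiling(len / maxEdgePx))
    t <- seq(0, 1, length.out = k + 1L)[-(k + 1L)]
    out[[i]] <- cbind(a[1] + t * (b[1] - a[1]), a[2] + t * (b[2] - a[2]))
  }
  res <- do.call(rbind, out)
  dimnames(res) <- list(NULL, c("x", "y"))
  res
}

## polygon centroid (vertex mean is biased; use area-weighted centroid)
polygonCentroid <- function(polygon) {
  x <- polygon[, 1]; y <- polygon[, 2]
  x2 <- c(x[-1], x[1]); y2 <- c(y[-1], y[1])
  cr <- x * y2 - x2 * y
  a <- sum(cr) / 2
  if (abs(a) < 1e-12) return(c(mean(x), mean(y)))
  c(sum((x + x2) * cr) / (6 * a), sum((y + y2) * cr) / (6 * a))
}
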