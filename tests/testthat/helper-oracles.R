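# Independent reference implementations used as oracles. Each is written
# along a different algorithmic path than the package code it checks.

# --- brute-force .roi parser: byte arithmetic, no readBin ---------------
oracleShort <- function(bytes, off) {  # off 0-based, big-endian int16
  v <- 256L * as.integer(bytes[off + 1L]) + as.integer(bytes[off + 2L])
  if (v >= 32768L) v - 65536L else v
}
oracleUShort <- function(bytes, off) {
  256L * as.integer(bytes[off + 1L]) + as.integer(bytes[off + 2L])
}
oracleInt <- function(bytes, off) {
  sum(as.integer(bytes[off + 1:4]) * c(16777216, 65536, 256, 1))
}
oracleDecodeRoi <- function(bytes) {
  stopifnot(rawToChar(bytes[1:4]) == "Iout")
  typeByte <- as.integer(bytes[7])
  stopifnot(typeByte %in% c(0L, 7L))
  top <- oracleShort(bytes, 8L); left <- oracleShort(bytes, 10L)
  n <- oracleUShort(bytes, 16L)
  xs <- vapply(seq_len(n) - 1L, function(i) oracleShort(bytes, 64L + 2L * i), integer(1))
  ys <- vapply(seq_len(n) - 1L, function(i) oracleShort(bytes, 64L + 2L * n + 2L * i), integer(1))
  hdr2 <- oracleInt(bytes, 60L)
  name <- NA_character_
  if (hdr2 > 0) {
    nameOff <- oracleInt(bytes, hdr2 + 16L)
    nameLen <- oracleInt(bytes, hdr2 + 20L)
    if (nameOff > 0 && nameLen > 0)
      name <- intToUtf8(vapply(seq_len(nameLen) - 1L,
                               function(i) oracleUShort(bytes, nameOff + 2L * i),
                               integer(1)))
  }
  list(name = name, kind = if (typeByte == 0L) "polygon" else "freehand",
       x = as.numeric(xs + left), y = as.numeric(ys + top))
}

# --- per-pixel even-odd rasterization oracle ----------------------------
# Accumulates crossing counts per edge over the full pixel-center grid;
# same tie-break convention as the package (half-open in y, strict in x).
oracleRaster <- function(poly, height, width) {
  px <- rep((0:(width - 1)) + 0.5, each = height)
  py <- rep((0:(height - 1)) + 0.5, times = width)
  x1 <- poly[, 1]; y1 <- poly[, 2]
  x2 <- c(x1[-1], x1[1]); y2 <- c(y1[-1], y1[1])
  cross <- integer(length(px))
  for (i in seq_along(x1)) {
    if (y1[i] == y2[i]) next
    cond <- (y1[i] > py) != (y2[i] > py)
    xint <- x1[i] + (py - y1[i]) * (x2[i] - x1[i]) / (y2[i] - y1[i])
    cross <- cross + (cond & px < xint)
  }
  matrix(cross %% 2L == 1L, height, width)
}

# --- scalar stack-based flood fill component labeling -------------------
oracleLabel <- function(mask, connectivity = 8) {
  h <- nrow(mask); w <- ncol(mask)
  lab <- matrix(0L, h, w)
  nb <- if (connectivity == 8)
    rbind(c(-1, -1), c(-1, 0), c(-1, 1), c(0, -1), c(0, 1), c(1, -1), c(1, 0), c(1, 1))
  else rbind(c(-1, 0), c(0, -1), c(0, 1), c(1, 0))
  k <- 0L
  for (r in seq_len(h)) for (c in seq_len(w)) {
    if (!mask[r, c] || lab[r, c] != 0L) next
    k <- k + 1L
    stack <- list(c(r, c)); lab[r, c] <- k
    while (length(stack)) {
      p <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
      for (j in seq_len(nrow(nb))) {
        rr <- p[1] + nb[j, 1]; cc <- p[2] + nb[j, 2]
        if (rr >= 1 && rr <= h && cc >= 1 && cc <= w &&
            mask[rr, cc] && lab[rr, cc] == 0L) {
          lab[rr, cc] <- k
          stack[[length(stack) + 1L]] <- c(rr, cc)
        }
      }
    }
  }
  lab
}

# --- coincidence-matrix Krippendorff's alpha (interval) -----------------
oracleAlpha <- function(values) {
  values <- as.matrix(values)
  keep <- rowSums(!is.na(values)) >= 2L
  values <- values[keep, , drop = FALSE]
  uv <- sort(unique(values[!is.na(values)]))
  q <- length(uv)
  co <- matrix(0, q, q)
  for (u in seq_len(nrow(values))) {
    x <- values[u, !is.na(values[u, ])]
    m <- length(x)
    for (i in seq_len(m)) for (j in seq_len(m)) {
      if (i == j) next
      ci <- match(x[i], uv); cj <- match(x[j], uv)
      co[ci, cj] <- co[ci, cj] + 1 / (m - 1)
    }
  }
  n <- sum(co)
  nc <- rowSums(co)
  delta <- outer(uv, uv, function(a, b) (a - b)^2)
  Do <- sum(co * delta) / n
  De <- sum(outer(nc, nc) * delta) / (n * (n - 1))
  list(alpha = 1 - Do / De, Do = Do, De = De, n = n)
}

# --- random simple (star-shaped) polygon generator ----------------------
randomSimplePolygon <- function(nVerts, width, height, margin = 2) {
  cx <- runif(1, width * 0.3, width * 0.7)
  cy <- runif(1, height * 0.3, height * 0.7)
  rmax <- min(cx, cy, width - cx, height - cy) - margin
  ang <- sort(runif(nVerts, 0, 2 * pi))
  rad <- runif(nVerts, 0.3 * rmax, rmax)
  cbind(x = cx + rad * cos(ang), y = cy + rad * sin(ang))
}

# random RoiRecord with integer vertices
randomRoiRecord <- function(name, kind = "polygon", maxCoord = 500) {
  n <- sample(3:40, 1)
  poly <- round(randomSimplePolygon(n, maxCoord, maxCoord))
  # ensure at least 3 distinct vertices after rounding
  while (nrow(unique(poly)) < 3) poly <- round(randomSimplePolygon(n, maxCoord, maxCoord))
  RoiRecord(name, poly, kind = kind)
}
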