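## Deterministic synthetic-data generator: plates, punctate blob images
## with known per-region counts, fill images with known label fractions,
## and perturbed rater traces. Every generator threads one integer seed
## through a local RNG stream (the caller's RNG state is saved and
## restored), so fixtures are bit-reproducible from (args, seed).

withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Generate a synthetic atlas plate
#'
#' Lays `nRegions` disjoint jittered-rectangle regions named `R01..Rnn` on
#' a grid over the canvas. Each region sits inside its own grid cell with a
#' margin, so pairwise raster intersections are empty by construction.
#'
#' @param nRegions Number of regions, >= 1.
#' @param width,height Canvas (reference) dimensions in px; every grid cell
#'   must be at least 10x10 px.
#' @param seed Integer seed.
#' @return An [AtlasPlate-class].
#' @examples
#' synthPlate(12, 400, 300, seed = 7)
#' @export
synthPlate <- function(nRegions, width, height, seed = 1) {
  stopifnot(nRegions >= 1)
  nc <- max(1L, ceiling(sqrt(nRegions * width / height)))
  nr <- ceiling(nRegions / nc)
  cw <- floor(width / nc); ch <- floor(height / nr)
  if (cw < 10 || ch < 10)
    stop("canvas too small: ", nRegions, " regions on ", width, "x", height,
         " gives ", cw, "x", ch, " px cells (need >= 10x10)")
  withSeed(seed, {
    regs <- vector("list", nRegions)
    for (k in seq_len(nRegions)) {
      gc <- (k - 1L) %% nc; gr <- (k - 1L) %/% nc
      # inset rectangle with jittered edges; margin keeps neighbors disjoint
      jx <- stats::runif(2, 0, 0.15 * cw); jy <- stats::runif(2, 0, 0.15 * ch)
      x0 <- gc * cw + 2 + jx[1]; x1 <- (gc + 1) * cw - 2 - jx[2]
      y0 <- gr * ch + 2 + jy[1]; y1 <- (gr + 1) * ch - 2 - jy[2]
      # inward-jittered edge midpoints make the outline polygonal, not boxy
      ex <- stats::runif(2, 0, 0.1 * (x1 - x0)); ey <- stats::runif(2, 0, 0.1 * (y1 - y0))
      poly <- rbind(
        c(x0, y0), c((x0 + x1) / 2, y0 + ey[1]), c(x1, y0),
        c(x1 - ex[1], (y0 + y1) / 2), c(x1, y1),
        c((x0 + x1) / 2, y1 - ey[2]), c(x0, y1),
        c(x0 + ex[2], (y0 + y1) / 2))
      regs[[k]] <- Region(sprintf("R%02d", k), poly)
    }
    AtlasPlate(sprintf("synth_%d", seed), width, height, regs)
  })
}

## pixel offsets of a rasterized disk of the given radius around a center
diskOffsets <- function(radius) {
  r <- ceiling(radius)
  g <- expand.grid(dr = -r:r, dc = -r:r)
  g[g$dr^2 + g$dc^2 <= radius^2, , drop = FALSE]
}

#' Generate a punctate blob image with known per-region counts
#'
#' Emulates a punctate nuclear label (c-Fos-like): filled disks of
#' intensity 255 on a dim noisy background. Blob centers are placed at
#' pixel centers at least `radius` inside their region (no cross-region
#' leakage) and pairwise separated by more than one diameter (no merged
#' objects), so thresholding at [128, 255] plus a size filter recovers
#' every blob exactly at `noiseSd = 0`, and each object's centroid equals
#' its seeded center.
#'
#' @param plate An [AtlasPlate-class].
#' @param counts Named integer vector (region abbrev -> blob count).
#' @param radius Disk radius in px.
#' @param noiseSd Gaussian noise SD added to the whole image (clipped to
#'   [0, 255]).
#' @param background Background intensity.
#' @param seed Integer seed.
#' @return List with `image` (numeric matrix) and `truth` (list: `counts`,
#'   `centroids` data.frame, `seed`).
#' @export
synthBlobImage <- function(plate, counts, radius = 3, noiseSd = 0,
                           background = 20, seed = 1) {
  stopifnot(is(plate, "AtlasPlate"))
  h <- plate@refHeight; w <- plate@refWidth
  abbrevs <- regionNames(plate)
  stopifnot(all(names(counts) %in% abbrevs))
  offs <- diskOffsets(radius)
  minSep2 <- (2 * radius + 2)^2
  withSeed(seed, {
    img <- matrix(background, h, w)
    cents <- list()
    for (ab in names(counts)) {
      nWant <- counts[[ab]]
      if (nWant == 0) next
      reg <- plate@regions[[match(ab, abbrevs)]]
      ras <- rasterizePolygon(reg@polygon, h, w)
      # candidate centers: pixels whose whole disk lies inside the raster
      cand <- which(ras)
      rr <- (cand - 1L) %% h; cc <- (cand - 1L) %/% h
      ok <- rep(TRUE, length(cand))
      for (i in seq_len(nrow(offs))) {
        r2 <- rr + offs$dr[i]; c2 <- cc + offs$dc[i]
        ok <- ok & r2 >= 0L & r2 < h & c2 >= 0L & c2 < w
        sel <- which(ok)
        if (!length(sel)) break
        ok[sel] <- ras[cbind(r2[sel] + 1L, c2[sel] + 1L)]
      }
      cand <- cand[ok]; rr <- rr[ok]; cc <- cc[ok]
      perm <- sample.int(length(cand))
      chosenR <- integer(0); chosenC <- integer(0)
      for (i in perm) {
        if (length(chosenR) == nWant) break
        if (length(chosenR) &&
            any((chosenR - rr[i])^2 + (chosenC - cc[i])^2 < minSep2)) next
        chosenR <- c(chosenR, rr[i]); chosenC <- c(chosenC, cc[i])
      }
      if (length(chosenR) < nWant)
        stop("infeasible packing: region '", ab, "' fits only ",
             length(chosenR), " of ", nWant, " blobs")
      for (i in seq_along(chosenR)) {
        pr <- chosenR[i] + offs$dr + 1L; pc <- chosenC[i] + offs$dc + 1L
        img[cbind(pr, pc)] <- 255
      }
      cents[[ab]] <- data.frame(region = ab, x = chosenC + 0.5, y = chosenR + 0.5)
    }
    if (noiseSd > 0)
      img <- matrix(pmin(255, pmax(0, img + stats::rnorm(h * w, 0, noiseSd))), h, w)
    full <- stats::setNames(rep(0L, length(abbrevs)), abbrevs)
    full[names(counts)] <- as.integer(counts)
    list(image = img,
         truth = list(counts = full,
                      centroids = do.call(rbind, c(cents, list(make.row.names = FALSE))),
                      seed = seed))
  })
}

#' Generate a fill-fraction label mask with known per-region percent area
#'
#' Emulates an area label (vessel-like): within each region's raster,
#' exactly `round(fraction * A)` pixels are set true (a seed-deterministic
#' random subset), so the volumetric percent area equals the recorded
#' achieved fraction exactly.
#'
#' @param plate An [AtlasPlate-class].
#' @param fractions Named numeric vector in [0, 1] (region abbrev ->
#'   target fill fraction).
#' @param seed Integer seed.
#' @return List with `mask` (logical matrix) and `truth` (list:
#'   `percent` named vector of achieved percent areas, `seed`).
#' @export
synthFillImage <- function(plate, fractions, seed = 1) {
  stopifnot(is(plate, "AtlasPlate"), all(fractions >= 0 & fractions <= 1))
  h <- plate@refHeight; w <- plate@refWidth
  abbrevs <- regionNames(plate)
  stopifnot(all(names(fractions) %in% abbrevs))
  withSeed(seed, {
    mask <- matrix(FALSE, h, w)
    achieved <- stats::setNames(rep(NA_real_, length(fractions)), names(fractions))
    for (ab in names(fractions)) {
      reg <- plate@regions[[match(ab, abbrevs)]]
      idx <- which(rasterizePolygon(reg@polygon, h, w))
      A <- length(idx)
      k <- round(fractions[[ab]] * A)
      if (k > 0) mask[sample(idx, k)] <- TRUE
      achieved[ab] <- 100 * k / A
    }
    list(mask = mask, truth = list(percent = achieved, seed = seed))
  })
}

#' Perturb a polygon with smooth low-frequency noise
#'
#' Simulates an independent rater's trace: vertices are displaced by a
#' low-order Fourier series along the outline (harmonics 1-3) scaled so the
#' RMS displacement is approximately `magnitudePx`. Magnitude 0 returns the
#' input unchanged. If the perturbed outline self-intersects, the
#' displacement is halved until it is simple again; persistent failure is
#' an error.
#'
#' @param polygon Two-column vertex matrix.
#' @param magnitudePx Target RMS vertex displacement in px.
#' @param seed Integer seed.
#' @return Perturbed vertex matrix.
#' @export
perturbPolygon <- function(polygon, magnitudePx, seed = 1) {
  stopifnot(magnitudePx >= 0)
  polygon <- as.matrix(polygon)
  if (magnitudePx == 0) return(polygon)
  n <- nrow(polygon)
  withSeed(seed, {
    t <- 2 * pi * (seq_len(n) - 1L) / n
    disp <- matrix(0, n, 2)
    for (dim in 1:2) {
      d <- numeric(n)
      for (hh in 1:3)
        d <- d + stats::rnorm(1, 0, 1 / hh) * cos(hh * t + stats::runif(1, 0, 2 * pi))
      disp[, dim] <- d
    }
    rms <- sqrt(mean(rowSums(disp^2)))
    if (rms > 0) disp <- disp * magnitudePx / rms
    scale <- 1
    for (i in 1:12) {
      cand <- polygon + scale * disp
      if (polygonIsSimple(cand)) return(cand)
      scale <- scale / 2
    }
    stop("perturbation produced invalid polygon")
  })
}
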