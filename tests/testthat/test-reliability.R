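sq <- function(x0, y0, w, h) rbind(c(x0, y0), c(x0 + w, y0), c(x0 + w, y0 + h), c(x0, y0 + h))

test_that("percentOverlap is the containment ratio on the pixel lattice", {
  ref <- sq(5, 5, 10, 10)
  expect_equal(percentOverlap(ref, ref, c(30, 30)), 100)
  expect_equal(percentOverlap(sq(5, 5, 8, 10), ref, c(30, 30)), 80)

  set.seed(51)
  for (rep in 1:10) {
    a <- randomSimplePolygon(sample(4:15, 1), 50, 50)
    b <- randomSimplePolygon(sample(4:15, 1), 50, 50)
    ra <- oracleRaster(a, 50, 50); rb <- oracleRaster(b, 50, 50)
    if (sum(rb) == 0) next
    expect_equal(percentOverlap(a, b, c(50, 50)), 100 * sum(ra & rb) / sum(rb))
  }
  far <- sq(200, 200, 5, 5)
  expect_error(percentOverlap(ref, far, c(30, 30)), "empty reference")
})

test_that("percentOverlap(A, B) = 100 iff raster(A) contains raster(B)", {
  outer <- sq(2, 2, 20, 20)
  inner <- sq(5, 5, 8, 8)
  expect_equal(percentOverlap(outer, inner, c(30, 30)), 100)
  expect_lt(percentOverlap(inner, outer, c(30, 30)), 100)
  # symmetric Dice option
  d <- percentOverlap(inner, outer, c(30, 30), dice = TRUE)
  expect_equal(d, 100 * 2 * 64 / (64 + 400))
})

test_that("union-combined group overlap reduces to |individual| / |union|", {
  dims <- c(40, 40)
  same <- list(r1 = sq(5, 5, 10, 10), r2 = sq(5, 5, 10, 10),
               r3 = sq(5, 5, 10, 10))
  expect_true(all(groupOverlap(same, dims) == 100))

  disjoint <- list(r1 = sq(2, 2, 10, 10), r2 = sq(20, 20, 10, 10))
  expect_true(all(groupOverlap(disjoint, dims) == 50))

  expect_error(groupOverlap(disjoint[1], dims), "at least 2 raters")

  # perturbed copies match the per-pixel oracle
  base <- sq(8, 8, 20, 20)
  traces <- lapply(1:4, function(i) perturbPolygon(base, 2, seed = 60 + i))
  names(traces) <- paste0("rater", 1:4)
  got <- groupOverlap(traces, dims)
  rasters <- lapply(traces, oracleRaster, height = 40, width = 40)
  un <- Reduce(`|`, rasters)
  ref <- vapply(rasters, function(r) 100 * sum(r & un) / sum(un), numeric(1))
  expect_equal(unname(got), unname(ref))
  expect_true(all(got > 0 & got <= 100))

  # intersection reading uses the common core as reference
  gi <- groupOverlap(traces, dims, combine = "intersection")
  expect_true(all(gi == 100))  # every trace contains the intersection
})

test_that("summedAreaTable sums like regions across images per rater", {
  one <- data.frame(image = "i1", rater = "r1", region = "AMY")
  one$polygon <- list(sq(0, 0, 10, 10))
  expect_equal(summedAreaTable(one, c(30, 30)),
               matrix(100, 1, 1, dimnames = list("r1", "AMY")))

  three <- data.frame(image = c("i1", "i2", "i3"), rater = "r1", region = "AMY")
  three$polygon <- list(sq(0, 0, 10, 10), sq(5, 5, 10, 10), sq(2, 2, 10, 10))
  expect_equal(as.numeric(summedAreaTable(three, c(30, 30))), 300)

  # 4 raters x 3 regions fixture vs brute-force double loop; missing = NA
  set.seed(71)
  regionsV <- c("AMY", "HPF", "TH")
  rows <- list()
  for (im in c("i1", "i2")) for (r in paste0("r", 1:4)) for (g in regionsV) {
    if (r == "r4" && g == "TH") next  # r4 never traced TH
    rows[[length(rows) + 1L]] <- data.frame(image = im, rater = r, region = g)
  }
  traces <- do.call(rbind, rows)
  traces$polygon <- lapply(seq_len(nrow(traces)), function(i)
    sq(sample(0:10, 1), sample(0:10, 1), sample(5:15, 1), sample(5:15, 1)))
  tab <- summedAreaTable(traces, c(40, 40))
  for (r in paste0("r", 1:4)) for (g in regionsV) {
    idx <- which(traces$rater == r & traces$region == g)
    if (!length(idx)) expect_true(is.na(tab[r, g]))
    else expect_equal(tab[r, g],
                      sum(vapply(idx, function(i)
                        sum(oracleRaster(traces$polygon[[i]], 40, 40)), numeric(1))))
  }
  expect_true(is.na(tab["r4", "TH"]))
})

test_that("krippendorffAlpha implements interval alpha exactly", {
  # perfect agreement
  res <- krippendorffAlpha(rbind(c(1, 1), c(2, 2), c(3, 3)))
  expect_identical(observedDisagreement(res), 0)
  expect_equal(alphaValue(res), 1)

  # all pairable values identical -> undefined
  expect_error(krippendorffAlpha(rbind(c(5, 5), c(5, 5))), "alpha undefined")
  expect_error(krippendorffAlpha(rbind(c(1, NA), c(NA, 2))), "at least 2 ratings")

  # fixed fixture vs coincidence-matrix oracle
  m <- rbind(c(1, 2), c(2, 2), c(3, 4), c(4, 4))
  res <- krippendorffAlpha(m)
  ref <- oracleAlpha(m)
  expect_equal(alphaValue(res), ref$alpha, tolerance = 1e-12)
  expect_equal(observedDisagreement(res), ref$Do, tolerance = 1e-12)
  expect_equal(expectedDisagreement(res), ref$De, tolerance = 1e-12)
  expect_identical(nPairable(res), as.integer(ref$n))
})

test_that("alpha matches the coincidence-matrix oracle on random missing-data matrices", {
  set.seed(81)
  for (rep in 1:50) {
    nu <- sample(3:10, 1); nr <- sample(2:5, 1)
    m <- matrix(sample(1:6, nu * nr, replace = TRUE), nu, nr)
    m[runif(nu * nr) < 0.25] <- NA
    ok <- sum(rowSums(!is.na(m)) >= 2) >= 1
    if (!ok) next
    vals <- m[rowSums(!is.na(m)) >= 2, ]
    if (length(unique(vals[!is.na(vals)])) < 2) next
    expect_equal(alphaValue(krippendorffAlpha(m)), oracleAlpha(m)$alpha,
                 tolerance = 1e-12)
  }
})

test_that("interval alpha is invariant under affine value rescaling", {
  set.seed(91)
  m <- matrix(rnorm(20, 50, 10), 5, 4)
  m[2, 3] <- NA
  a0 <- alphaValue(krippendorffAlpha(m))
  for (ab in list(c(2, 0), c(0.5, 10), c(-3, 100))) {
    expect_equal(alphaValue(krippendorffAlpha(ab[1] * m + ab[2])), a0,
                 tolerance = 1e-9)
  }
})

test_that("group overlap degrades monotonically with rater perturbation", {
  base <- sq(20, 20, 60, 60)
  dims <- c(100, 100)
  mags <- c(1, 2, 4, 8)
  meanOv <- vapply(mags, function(m) {
    traces <- lapply(1:4, function(i) perturbPolygon(base, m, seed = 300 + i))
    mean(groupOverlap(traces, dims))
  }, numeric(1))
  expect_true(all(diff(meanOv) <= 0))
  expect_lte(stats::cor(mags, meanOv, method = "spearman"), 0)
})
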