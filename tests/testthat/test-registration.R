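test_that("linearFit scales vertices and areas analytically", {
  plate <- synthPlate(4, 100, 100, seed = 2)
  # identity when target dims equal reference dims
  same <- linearFit(plate, 100, 100)
  expect_identical(same$fit, list(sx = 1, sy = 1))
  for (i in seq_along(regions(plate)))
    expect_equal(regions(same$plate)[[i]]@polygon, regions(plate)[[i]]@polygon)

  # 100x100 -> 200x50: (10, 20) -> (20, 10); area factor sx*sy = 1
  sq <- AtlasPlate("s", 100, 100, list(Region("A", rbind(c(10, 20), c(30, 20), c(10, 40)))))
  fit <- linearFit(sq, 200, 50)
  expect_equal(regions(fit$plate)[[1]]@polygon[1, ], c(x = 20, y = 10))
  expect_equal(shoelaceArea(regions(fit$plate)[[1]]@polygon),
               shoelaceArea(regions(sq)[[1]]@polygon))

  # shoelace areas scale by exactly sx * sy on a random plate
  plate <- synthPlate(6, 120, 90, seed = 9)
  fit <- linearFit(plate, 360, 180)   # sx = 3, sy = 2
  for (i in seq_along(regions(plate)))
    expect_equal(shoelaceArea(regions(fit$plate)[[i]]@polygon),
                 6 * shoelaceArea(regions(plate)[[i]]@polygon))

  expect_error(linearFit(plate, 0, 100), "positive")
})

test_that("freeformWarp obeys the 0/1/2/3-pair contracts", {
  plate <- synthPlate(3, 150, 100, seed = 5)
  # zero pairs: identity vertex-for-vertex
  expect_identical(freeformWarp(plate, NULL), plate)
  w0 <- freeformWarp(plate, data.frame(src_x = numeric(0), src_y = numeric(0),
                                       dst_x = numeric(0), dst_y = numeric(0)))
  expect_identical(w0, plate)

  # one pair: global translation
  w1 <- freeformWarp(plate, data.frame(src_x = 0, src_y = 0, dst_x = 5, dst_y = -3))
  for (i in seq_along(regions(plate)))
    expect_equal(regions(w1)[[i]]@polygon,
                 sweep(regions(plate)[[i]]@polygon, 2, c(-5, 3)))

  # three pairs defining an affine map are reproduced at arbitrary probes
  pairs <- data.frame(src_x = c(0, 10, 0), src_y = c(0, 0, 10),
                      dst_x = c(0, 20, 0), dst_y = c(0, 0, 5))
  probe <- AtlasPlate("p", 150, 100,
                      list(Region("A", rbind(c(5, 5), c(7, 5), c(5, 7)))))
  w3 <- freeformWarp(probe, pairs)
  expect_equal(regions(w3)[[1]]@polygon[1, ], c(x = 10, y = 2.5),
               tolerance = 1e-9)
  expect_equal(regions(w3)[[1]]@polygon[2, ], c(x = 14, y = 2.5),
               tolerance = 1e-9)

  # two pairs: exact interpolation at both controls
  p2 <- data.frame(src_x = c(10, 100), src_y = c(10, 80),
                   dst_x = c(15, 95), dst_y = c(8, 85))
  probe2 <- AtlasPlate("q", 150, 100,
                       list(Region("A", rbind(c(10, 10), c(100, 80), c(50, 20)))))
  w2 <- freeformWarp(probe2, p2)
  expect_equal(regions(w2)[[1]]@polygon[1, ], c(x = 15, y = 8), tolerance = 1e-9)
  expect_equal(regions(w2)[[1]]@polygon[2, ], c(x = 95, y = 85), tolerance = 1e-9)
})

test_that("warp reproduces control points to 1e-9 and affine maps to 1e-6", {
  set.seed(31)
  for (rep in 1:10) {
    k <- sample(3:8, 1)
    src <- cbind(runif(k, 0, 200), runif(k, 0, 200))
    while (qr(cbind(1, src))$rank < 3) src <- cbind(runif(k, 0, 200), runif(k, 0, 200))
    dst <- src + matrix(rnorm(2 * k, 0, 10), k, 2)
    plate <- AtlasPlate("w", 200, 200, list(Region("A", src)))
    warped <- freeformWarp(plate, data.frame(src_x = src[, 1], src_y = src[, 2],
                                             dst_x = dst[, 1], dst_y = dst[, 2]))
    expect_lt(max(abs(regions(warped)[[1]]@polygon - dst)), 1e-9)
  }
  # random affine sampled at >= 3 points reproduces everywhere
  for (rep in 1:10) {
    A <- matrix(rnorm(4, 0, 1), 2, 2); b <- rnorm(2, 0, 5)
    while (abs(det(A)) < 0.1) A <- matrix(rnorm(4, 0, 1), 2, 2)
    k <- sample(3:6, 1)
    src <- cbind(runif(k, 0, 100), runif(k, 0, 100))
    while (qr(cbind(1, src))$rank < 3) src <- cbind(runif(k, 0, 100), runif(k, 0, 100))
    dst <- src %*% t(A) + rep(1, k) %o% b
    probes <- cbind(runif(20, -50, 150), runif(20, -50, 150))
    plate <- AtlasPlate("w", 200, 200, list(Region("A", probes)))
    warped <- freeformWarp(plate, data.frame(src_x = src[, 1], src_y = src[, 2],
                                             dst_x = dst[, 1], dst_y = dst[, 2]))
    expected <- probes %*% t(A) + rep(1, 20) %o% b
    expect_lt(max(abs(regions(warped)[[1]]@polygon - expected)), 1e-6)
  }
})

test_that("warp with identity pairs on a grid is the identity", {
  g <- expand.grid(x = seq(10, 140, by = 30), y = seq(10, 90, by = 20))
  plate <- synthPlate(4, 150, 100, seed = 8)
  w <- freeformWarp(plate, data.frame(src_x = g$x, src_y = g$y,
                                      dst_x = g$x, dst_y = g$y))
  for (i in seq_along(regions(plate)))
    expect_lt(max(abs(regions(w)[[i]]@polygon - regions(plate)[[i]]@polygon)), 1e-9)
})

test_that("degenerate control configurations are rejected", {
  plate <- synthPlate(1, 50, 50, seed = 1)
  dup <- data.frame(src_x = c(1, 1), src_y = c(2, 2), dst_x = c(3, 4), dst_y = c(5, 6))
  expect_error(freeformWarp(plate, dup), "duplicate control source")
  coll <- data.frame(src_x = c(0, 10, 20), src_y = c(0, 10, 20),
                     dst_x = c(0, 10, 20), dst_y = c(1, 11, 21))
  expect_error(freeformWarp(plate, coll), "degenerate control configuration")
})

test_that("fitted plates export, log and re-load up to quantization", {
  dir <- withr::local_tempdir()
  plate <- synthPlate(12, 400, 300, seed = 6)
  fitted <- linearFit(plate, 800, 600)$plate
  path <- exportFittedPlate(fitted, "imgA", dir)
  expect_true(file.exists(path))
  back <- readRoiArchive(path)
  expect_length(back, 12)
  for (i in 1:12)
    expect_equal(roiCoords(back[[i]]),
                 round(regions(fitted)[[i]]@polygon), ignore_attr = TRUE)
  exportFittedPlate(fitted, "imgB", dir)
  log <- utils::read.csv(file.path(dir, "fitted_plates_log.csv"))
  expect_identical(log$image_id, c("imgA", "imgB"))

  bad <- AtlasPlate("b", 400, 300,
                    list(Region("X", rbind(c(0, 0), c(10, 10), c(10, 0), c(0, 10)))))
  expect_error(exportFittedPlate(bad, "imgC", dir), "self-intersecting")
})

test_that("overlay recolors exactly the 1-px outline pixels", {
  img <- matrix(0, 40, 40)
  sq <- AtlasPlate("s", 40, 40,
                   list(Region("A", rbind(c(5, 5), c(25, 5), c(25, 25), c(5, 25)))))
  ov <- renderOverlay(img, sq, color = c(1, 0, 0))
  ras <- oracleRaster(regions(sq)[[1]]@polygon, 40, 40)
  # brute-force outline: raster pixels with a 4-neighbor outside
  edge <- matrix(FALSE, 40, 40)
  for (r in 1:40) for (c in 1:40) {
    if (!ras[r, c]) next
    nb <- c(r > 1 && ras[r - 1, c], r < 40 && ras[r + 1, c],
            c > 1 && ras[r, c - 1], c < 40 && ras[r, c + 1])
    if (!all(nb)) edge[r, c] <- TRUE
  }
  expect_identical(ov[, , 1] == 1, edge)        # red channel set on outline
  expect_identical(ov[, , 2] == 0, matrix(TRUE, 40, 40))  # untouched elsewhere

  # empty plate: unchanged as RGB
  none <- AtlasPlate("n", 40, 40, list())
  ov0 <- renderOverlay(img, none)
  expect_identical(dim(ov0), c(40L, 40L, 3L))
  expect_true(all(ov0 == 0))

  expect_error(renderOverlay(matrix(0, 30, 40), sq), "do not match")
})
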