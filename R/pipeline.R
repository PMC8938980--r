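## Batch front-end: run the full register -> segment -> quantify workflow
## over a directory of images, mirroring the interactive workflow (choose
## analysis type, fit the assigned plate, adjust, apply to the binarized
## label, write per-region outputs).

#' Assemble a pipeline run configuration
#'
#' Exactly one of `masksDir` (pre-binarized masks, same file names as the
#' images) or `threshold` (intensity bounds applied to the raw images) must
#' be supplied.
#'
#' @param imagesDir Directory of input images (.tif/.tiff/.png), processed
#'   in lexicographic filename order.
#' @param atlasManifest Path to the atlas manifest CSV (see [loadAtlas()]).
#' @param assignCsv Path to the image assignment CSV with header
#'   `image,plate_id[,controls]`; `controls` optionally names a CSV of
#'   `src_x,src_y,dst_x,dst_y` control pairs (path relative to the
#'   assignment file).
#' @param outDir Output directory.
#' @param mode `"counts"` or `"volumetric"`.
#' @param masksDir Optional directory of pre-binarized masks.
#' @param threshold Optional `c(lo, hi)` intensity bounds.
#' @param sizeRange Object size bounds `c(min, max)` in px^2 applied after
#'   thresholding (ignored with `masksDir`).
#' @param umPerPx Optional pixel size in micrometres.
#' @param range Optional `c(first, last)` slice of the lexicographic image
#'   order.
#' @param overlay Write RGB overlay PNGs of the fitted outlines.
#' @param failFast Error on the first problem image instead of skipping it.
#' @return A `runConfig` list.
#' @export
runConfig <- function(imagesDir, atlasManifest, assignCsv, outDir,
                      mode = c("counts", "volumetric"),
                      masksDir = NULL, threshold = NULL,
                      sizeRange = c(1, Inf), umPerPx = NULL, range = NULL,
                      overlay = TRUE, failFast = FALSE) {
  mode <- match.arg(mode)
  if (is.null(masksDir) == is.null(threshold))
    stop("supply exactly one of masksDir or threshold")
  structure(list(imagesDir = imagesDir, atlasManifest = atlasManifest,
                 assignCsv = assignCsv, outDir = outDir, mode = mode,
                 masksDir = masksDir, threshold = threshold,
                 sizeRange = sizeRange, umPerPx = umPerPx, range = range,
                 overlay = overlay, failFast = failFast),
            class = "runConfig")
}

#' Run the batch pipeline
#'
#' For each assigned image, in lexicographic filename order: load the
#' assigned plate, [linearFit()] it to the image dimensions, apply any
#' control-point [freeformWarp()], segment the label (or load the
#' pre-binarized mask), [quantifyImage()], and write the per-image results
#' CSV, fitted-plate ROI archive, and overlay PNG. Images without an
#' assignment or whose processing fails are skipped with a warning (or stop
#' the run with `failFast`). Re-running an identical configuration over
#' identical inputs reproduces the result CSVs byte for byte.
#'
#' @param config A [runConfig()] list.
#' @return Invisibly, a summary `data.frame` (image, status, detail); also
#'   written to `<outDir>/summary.csv`.
#' @export
runPipeline <- function(config) {
  stopifnot(inherits(config, "runConfig"))
  atlas <- loadAtlas(config$atlasManifest)
  assign <- utils::read.csv(config$assignCsv, stringsAsFactors = FALSE)
  if (!all(c("image", "plate_id") %in% names(assign)))
    stop("assignment CSV needs columns image, plate_id")
  if (!dir.exists(config$outDir)) dir.create(config$outDir, recursive = TRUE)
  files <- sort(list.files(config$imagesDir, pattern = "\\.(tif|tiff|png)$",
                           ignore.case = TRUE))
  if (!is.null(config$range))
    files <- files[seq(max(1, config$range[1]),
                       min(length(files), config$range[2]))]
  status <- character(length(files)); detail <- character(length(files))
  for (i in seq_along(files)) {
    f <- files[i]
    id <- sub("\\.[^.]*$", "", f)
    res <- tryCatch({
      j <- match(id, sub("\\.[^.]*$", "", assign$image))
      if (is.na(j)) stop("no plate assignment")
      plate <- getPlate(atlas, assign$plate_id[j])
      img <- readImageGray(file.path(config$imagesDir, f))
      h <- nrow(img); w <- ncol(img)
      fitted <- linearFit(plate, w, h)$plate
      ctrlFile <- if ("controls" %in% names(assign)) assign$controls[j] else NA
      if (!is.na(ctrlFile) && nzchar(ctrlFile)) {
        cp <- ctrlFile
        if (!file.exists(cp)) cp <- file.path(dirname(config$assignCsv), ctrlFile)
        fitted <- freeformWarp(fitted, utils::read.csv(cp))
      }
      mask <- if (!is.null(config$masksDir)) {
        coerceBinary(readImageGray(file.path(config$masksDir, f)))
      } else {
        m <- thresholdMask(img, config$threshold[1], config$threshold[2])
        sizeFilter(m, config$sizeRange[1], config$sizeRange[2])
      }
      rows <- quantifyImage(mask, fitted, config$mode, config$umPerPx)
      writeResults(rows, id, file.path(config$outDir, paste0(id, "_results.csv")))
      exportFittedPlate(fitted, id, file.path(config$outDir, "fitted_plates"))
      if (isTRUE(config$overlay)) {
        ov <- renderOverlay(img, fitted)
        dir.create(file.path(config$outDir, "overlays"), showWarnings = FALSE)
        png::writePNG(ov, file.path(config$outDir, "overlays", paste0(id, ".png")))
      }
      sprintf("%s: %d regions, mode %s", plate@plateId, nrow(rows), config$mode)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      if (config$failFast) stop("image '", id, "': ", conditionMessage(res))
      warning("skipping image '", id, "': ", conditionMessage(res))
      status[i] <- "skipped"; detail[i] <- conditionMessage(res)
    } else {
      status[i] <- "processed"; detail[i] <- res
    }
    message(sprintf("[%s] %s (%s)", status[i], f, detail[i]))
  }
  summary <- data.frame(image = files, status = status, detail = detail,
                        stringsAsFactors = FALSE)
  utils::write.csv(summary, file.path(config$outDir, "summary.csv"),
                   row.names = FALSE)
  invisible(summary)
}

#' Write a complete synthetic scaffold directory
#'
#' Emits everything the batch pipeline needs, generated from one seed:
#' a synthetic plate as an ROI archive + manifest, blob images (TIFF), the
#' image assignment CSV, and a ground-truth JSON-like RDS-free text file
#' (CSV of per-region true counts per image). Usable directly by
#' [runPipeline()].
#'
#' @param dir Scaffold directory (created).
#' @param nImages Number of images.
#' @param nRegions Regions per plate.
#' @param width,height Image dimensions.
#' @param countRange Per-region blob count range (inclusive) sampled
#'   uniformly.
#' @param noiseSd Image noise SD.
#' @param seed Integer seed.
#' @return Invisibly, the truth `data.frame` (image, region, count).
#' @export
writeScaffold <- function(dir, nImages = 3, nRegions = 12, width = 400,
                          height = 300, countRange = c(0, 12), noiseSd = 0,
                          seed = 1) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "images"), showWarnings = FALSE)
  plate <- synthPlate(nRegions, width, height, seed)
  rois <- lapply(plate@regions, function(r) RoiRecord(r@abbrev, r@polygon))
  writeRoiArchive(rois, file.path(dir, "plate01.zip"))
  utils::write.csv(data.frame(plate_id = plate@plateId, archive = "plate01.zip",
                              ref_width = width, ref_height = height),
                   file.path(dir, "manifest.csv"), row.names = FALSE)
  truth <- list()
  assign <- data.frame(image = character(nImages), plate_id = plate@plateId)
  for (i in seq_len(nImages)) {
    id <- sprintf("img%02d", i)
    counts <- withSeed(seed * 1000L + i, {
      stats::setNames(sample(countRange[1]:countRange[2], nRegions, replace = TRUE),
                      regionNames(plate))
    })
    blob <- synthBlobImage(plate, counts, radius = 3, noiseSd = noiseSd,
                           seed = seed * 1000L + i)
    tiff::writeTIFF(blob$image / 255, file.path(dir, "images", paste0(id, ".tif")),
                    bits.per.sample = 8L)
    assign$image[i] <- paste0(id, ".tif")
    truth[[i]] <- data.frame(image = id, region = names(blob$truth$counts),
                             count = as.integer(blob$truth$counts))
  }
  utils::write.csv(assign, file.path(dir, "assign.csv"), row.names = FALSE)
  truth <- do.call(rbind, truth)
  utils::write.csv(truth, file.path(dir, "truth.csv"), row.names = FALSE)
  invisible(truth)
}
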