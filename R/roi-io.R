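## Bit-level codec for the ImageJ .roi format (polygon and freehand subset)
## and for ROI-set ZIP archives, the on-disk unit of an atlas plate.
##
## On-disk layout (all multi-byte integers big-endian):
##   bytes 0-3    magic "Iout"
##   bytes 4-5    version (int16; written as 228)
##   byte  6      type (0 = polygon, 7 = freehand; others rejected)
##   bytes 8-15   bounding box top, left, bottom, right (int16 each)
##   bytes 16-17  number of coordinates n (int16)
##   bytes 60-63  offset of the second header (int32; 0 when absent)
##   bytes 64..   n int16 x-offsets relative to left, then n int16 y-offsets
##                relative to top
##   header2      64-byte block; int32 name offset at +16, int32 name length
##                (in characters) at +20; name stored as 16-bit characters.

.roiTypeNames <- c("polygon", "rectangle", "oval", "line", "freeline",
                   "polyline", "noRoi", "freehand", "traced", "angle", "point")

readShortsBE <- function(raw, off, n = 1L, signed = TRUE) {
  readBin(raw[(off + 1L):(off + 2L * n)], "integer", n = n, size = 2L,
          endian = "big", signed = signed)
}

readIntBE <- function(raw, off) {
  readBin(raw[(off + 1L):(off + 4L)], "integer", size = 4L, endian = "big")
}

#' Decode a single ImageJ .roi record
#'
#' Parses the raw bytes of one `.roi` record into a [RoiRecord-class].
#' Only the polygon (type byte 0) and freehand (type byte 7) variants are
#' supported; any other type -- line, oval, point, composite, ... -- is
#' rejected loudly rather than approximated. Vertices are reconstructed as
#' absolute pixel coordinates (stored offsets plus the bounding-box
#' left/top). The region name is taken from the record's second header when
#' present, else from `fallbackName` (callers reading an archive pass the
#' ZIP entry stem).
#'
#' @param raw Raw vector holding one .roi record.
#' @param fallbackName Name to use when the record carries none.
#' @return A [RoiRecord-class].
#' @examples
#' tri <- RoiRecord("tri", rbind(c(0, 0), c(10, 0), c(0, 10)))
#' identical(roiCoords(decodeRoi(encodeRoi(tri))), roiCoords(tri))
#' @export
decodeRoi <- function(raw, fallbackName = "roi") {
  if (length(raw) < 64L || rawToChar(raw[1:4]) != "Iout")
    stop("not an ImageJ ROI (bad magic)")
  typeByte <- as.integer(raw[7L])
  if (!typeByte %in% c(0L, 7L)) {
    nm <- if (typeByte < length(.roiTypeNames)) .roiTypeNames[typeByte + 1L]
          else "unknown"
    stop("unsupported ROI type (byte ", typeByte, ", '", nm, "')")
  }
  kind <- if (typeByte == 0L) "polygon" else "freehand"
  top <- readShortsBE(raw, 8L); left <- readShortsBE(raw, 10L)
  n <- readShortsBE(raw, 16L, signed = FALSE)
  if (n < 3L) stop("ROI record has fewer than 3 vertices")
  if (length(raw) < 64L + 4L * n) stop("truncated ROI record")
  xs <- readShortsBE(raw, 64L, n) + left
  ys <- readShortsBE(raw, 64L + 2L * n, n) + top
  name <- NA_character_
  hdr2 <- readIntBE(raw, 60L)
  if (hdr2 > 0L && length(raw) >= hdr2 + 24L) {
    nameOff <- readIntBE(raw, hdr2 + 16L)
    nameLen <- readIntBE(raw, hdr2 + 20L)
    if (nameOff > 0L && nameLen > 0L && length(raw) >= nameOff + 2L * nameLen) {
      name <- intToUtf8(readShortsBE(raw, nameOff, nameLen, signed = FALSE))
    }
  }
  if (is.na(name) || !nzchar(name)) name <- fallbackName
  RoiRecord(name, cbind(x = xs, y = ys), kind = kind)
}

#' Encode a RoiRecord as ImageJ .roi bytes
#'
#' Writes the record in the layout read back by [decodeRoi()] (and by
#' ImageJ's own decoder). Vertex coordinates are quantized to the nearest
#' integer: the on-disk encoding stores int16 offsets, so sub-pixel
#' positions cannot be represented. Library-internal geometry stays float;
#' quantization happens here only.
#'
#' @param r A [RoiRecord-class].
#' @return Raw vector of the encoded record.
#' @export
encodeRoi <- function(r) {
  stopifnot(is(r, "RoiRecord"))
  validObject(r)
  xs <- as.integer(round(r@coords[, 1]))
  ys <- as.integer(round(r@coords[, 2]))
  left <- min(xs); top <- min(ys); right <- max(xs); bottom <- max(ys)
  if (any(c(xs, ys, left, top, right, bottom) > 32767L) ||
      any(c(xs, ys, left, top, right, bottom) < -32768L))
    stop("coordinate overflow: vertices exceed the int16 range of the .roi format")
  n <- length(xs)
  if (n > 65535L) stop("coordinate overflow: too many vertices for the .roi format")
  typeByte <- if (r@kind == "polygon") 0L else 7L
  hdr2Off <- 64L + 4L * n
  nameChars <- utf8ToInt(r@name)
  con <- rawConnection(raw(0), "wb")
  on.exit(close(con))
  wS <- function(v) writeBin(as.integer(v), con, size = 2L, endian = "big")
  wI <- function(v) writeBin(as.integer(v), con, size = 4L, endian = "big")
  writeBin(charToRaw("Iout"), con)
  wS(228L)                               # version
  writeBin(as.raw(c(typeByte, 0L)), con)
  wS(c(top, left, bottom, right))
  if (n > 32767L) wS(n - 65536L) else wS(n)   # unsigned int16
  writeBin(raw(42L), con)                # unused header fields (18..59)
  wI(hdr2Off)                            # header2 offset
  wS(xs - left)
  wS(ys - top)
  # header2: zeros except name offset/length
  writeBin(raw(16L), con)
  wI(hdr2Off + 64L)                      # name offset
  wI(length(nameChars))                  # name length
  writeBin(raw(40L), con)                # rest of header2
  wS(nameChars)
  rawConnectionValue(con)
}

#' Read an ROI-set ZIP archive
#'
#' Reads a ZIP archive whose entries are `.roi` records (one per region,
#' as saved by the ImageJ ROI Manager) and returns the decoded records in
#' archive order. A record's name comes from its embedded name when present,
#' else from the entry file name; when both exist and differ the embedded
#' name wins with a warning.
#'
#' @param path Path to the ZIP archive.
#' @return Named list of [RoiRecord-class] objects, in archive order.
#' @export
readRoiArchive <- function(path) {
  entries <- readZipEntries(path)
  keep <- grepl("\\.roi$", names(entries), ignore.case = TRUE)
  entries <- entries[keep]
  if (!length(entries)) stop("empty ROI set: no .roi entries in ", path)
  out <- vector("list", length(entries))
  nms <- character(length(entries))
  for (i in seq_along(entries)) {
    stem <- sub("\\.roi$", "", basename(names(entries)[i]), ignore.case = TRUE)
    rec <- decodeRoi(entries[[i]], fallbackName = stem)
    if (!identical(rec@name, stem) && nzchar(stem))
      warning("entry '", stem, "' carries embedded name '", rec@name,
              "'; using the embedded name")
    out[[i]] <- rec
    nms[i] <- rec@name
  }
  if (anyDuplicated(nms))
    stop("duplicate region name in archive: ",
         paste(unique(nms[duplicated(nms)]), collapse = ", "))
  names(out) <- nms
  out
}

#' Write an ROI-set ZIP archive
#'
#' Writes records in order as `<name>.roi` entries of a ZIP archive.
#' [readRoiArchive()] on the output reproduces the input up to the integer
#' quantization applied by [encodeRoi()].
#'
#' @param rois Named list of [RoiRecord-class] objects (names are ignored in
#'   favor of each record's own name).
#' @param path Output archive path.
#' @return `path`, invisibly.
#' @export
writeRoiArchive <- function(rois, path) {
  if (!length(rois)) stop("empty ROI set: refusing to write an archive with no regions")
  nms <- vapply(rois, function(r) r@name, character(1))
  if (anyDuplicated(nms))
    stop("duplicate region name: ", paste(unique(nms[duplicated(nms)]), collapse = ", "))
  entries <- lapply(rois, encodeRoi)
  names(entries) <- paste0(nms, ".roi")
  tryCatch(writeStoredZip(entries, path),
           error = function(e) stop("failed to write ROI archive '", path, "': ",
                                    conditionMessage(e)))
  invisible(path)
}
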