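## Minimal deterministic ZIP container support for ROI-set archives.
## Entries are stored uncompressed (method 0) with a fixed DOS timestamp so
## identical inputs produce byte-identical archives. Reading goes through
## utils::unzip, which also accepts deflate-compressed archives written by
## ImageJ or other tools.

# 256-entry CRC-32 lookup table (IEEE 802.3 polynomial, reflected)
.crcTable <- local({
  tab <- integer(256)
  for (n in 0:255) {
    cc <- n
    for (k in 1:8) {
      cc <- if (bitwAnd(cc, 1L) != 0L)
        bitwXor(bitwShiftR(cc, 1L), -306674912L)  # 0xEDB88320
      else bitwShiftR(cc, 1L)
    }
    tab[n + 1L] <- cc
  }
  tab
})

crc32 <- function(bytes) {
  crc <- -1L  # 0xFFFFFFFF
  b <- as.integer(bytes)
  for (i in seq_along(b)) {
    crc <- bitwXor(bitwShiftR(crc, 8L),
                   .crcTable[bitwAnd(bitwXor(crc, b[i]), 255L) + 1L])
  }
  bitwXor(crc, -1L)
}

writeLE <- function(con, value, size) {
  writeBin(as.integer(value), con, size = size, endian = "little")
}

## entries: named list of raw vectors (names become archive entry names)
writeStoredZip <- function(entries, path) {
  stopifnot(length(entries) > 0L, !is.null(names(entries)))
  con <- file(path, "wb")
  on.exit(close(con))
  offsets <- integer(length(entries))
  pos <- 0L
  dosDate <- 33L  # 1980-01-01, fixed for determinism
  crcs <- integer(length(entries))
  for (i in seq_along(entries)) {
    nm <- charToRaw(names(entries)[i])
    data <- entries[[i]]
    crcs[i] <- crc32(data)
    offsets[i] <- pos
    writeLE(con, 67324752L, 4)          # local header signature
    writeLE(con, 20L, 2)                # version needed
    writeLE(con, 0L, 2)                 # flags
    writeLE(con, 0L, 2)                 # method: stored
    writeLE(con, 0L, 2)                 # mod time
    writeLE(con, dosDate, 2)            # mod date
    writeLE(con, crcs[i], 4)
    writeLE(con, length(data), 4)       # compressed size
    writeLE(con, length(data), 4)       # uncompressed size
    writeLE(con, length(nm), 2)
    writeLE(con, 0L, 2)                 # extra length
    writeBin(nm, con)
    writeBin(data, con)
    pos <- pos + 30L + length(nm) + length(data)
  }
  cdStart <- pos
  for (i in seq_along(entries)) {
    nm <- charToRaw(names(entries)[i])
    data <- entries[[i]]
    writeLE(con, 33639248L, 4)          # central directory signature
    writeLE(con, 20L, 2)                # version made by
    writeLE(con, 20L, 2)                # version needed
    writeLE(con, 0L, 2)
    writeLE(con, 0L, 2)
    writeLE(con, 0L, 2)
    writeLE(con, dosDate, 2)
    writeLE(con, crcs[i], 4)
    writeLE(con, length(data), 4)
    writeLE(con, length(data), 4)
    writeLE(con, length(nm), 2)
    writeLE(con, 0L, 2)                 # extra
    writeLE(con, 0L, 2)                 # comment
    writeLE(con, 0L, 2)                 # disk number
    writeLE(con, 0L, 2)                 # internal attrs
    writeLE(con, 0L, 4)                 # external attrs
    writeLE(con, offsets[i], 4)
    writeBin(nm, con)
    pos <- pos + 46L + length(nm)
  }
  writeLE(con, 101010256L, 4)           # end of central directory
  writeLE(con, 0L, 2)
  writeLE(con, 0L, 2)
  writeLE(con, length(entries), 2)
  writeLE(con, length(entries), 2)
  writeLE(con, pos - cdStart, 4)
  writeLE(con, cdStart, 4)
  writeLE(con, 0L, 2)
  invisible(path)
}

## returns named list of raw vectors, in archive order
readZipEntries <- function(path) {
  if (!file.exists(path)) stop("archive not found: ", path)
  info <- utils::unzip(path, list = TRUE)
  if (nrow(info) == 0L) stop("empty ROI set: ", path)
  exdir <- tempfile("roiset")
  dir.create(exdir)
  on.exit(unlink(exdir, recursive = TRUE))
  utils::unzip(path, exdir = exdir)
  out <- vector("list", nrow(info))
  names(out) <- info$Name
  for (i in seq_len(nrow(info))) {
    f <- file.path(exdir, info$Name[i])
    out[[i]] <- readBin(f, "raw", n = file.info(f)$size)
  }
  out
}
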