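## Tiny 3x5 bitmap font used to burn region labels into overlay images.
## Covers A-Z and 0-9; any other character renders as a blank cell.

.font3x5 <- list(
  A = c("010","101","111","101","101"), B = c("110","101","110","101","110"),
  C = c("011","100","100","100","011"), D = c("110","101","101","101","110"),
  E = c("111","100","110","100","111"), F = c("111","100","110","100","100"),
  G = c("011","100","101","101","011"), H = c("101","101","111","101","101"),
  I = c("111","010","010","010","111"), J = c("001","001","001","101","010"),
  K = c("101","101","110","101","101"), L = c("100","100","100","100","111"),
  M = c("101","111","111","101","101"), N = c("101","111","101","101","101"),
  O = c("010","101","101","101","010"), P = c("110","101","110","100","100"),
  Q = c("010","101","101","011","001"), R = c("110","101","110","101","101"),
  S = c("011","100","010","001","110"), T = c("111","010","010","010","010"),
  U = c("101","101","101","101","111"), V = c("101","101","101","101","010"),
  W = c("101","101","111","111","101"), X = c("101","101","010","101","101"),
  Y = c("101","101","010","010","010"), Z = c("111","001","010","100","111"),
  `0` = c("010","101","101","101","010"), `1` = c("010","110","010","010","111"),
  `2` = c("110","001","010","100","111"), `3` = c("110","001","010","001","110"),
  `4` = c("101","101","111","001","001"), `5` = c("111","100","110","001","110"),
  `6` = c("011","100","110","101","010"), `7` = c("111","001","010","010","010"),
  `8` = c("010","101","010","101","010"), `9` = c("010","101","011","001","110")
)

## burn `text` centered at `center` = c(x, y) into an RGB array
burnText <- function(rgb, text, center, color) {
  h <- dim(rgb)[1]; w <- dim(rgb)[2]
  chars <- strsplit(toupper(text), "")[[1]]
  tw <- 4L * length(chars) - 1L
  x0 <- round(center[1] - tw / 2)
  y0 <- round(center[2] - 2.5)
  for (ci in seq_along(chars)) {
    glyph <- .font3x5[[chars[ci]]]
    if (is.null(glyph)) next
    gx <- x0 + 4L * (ci - 1L)
    for (gr in 1:5) {
      bits <- strsplit(glyph[gr], "")[[1]] == "1"
      for (gc in 1:3) {
        if (!bits[gc]) next
        r <- y0 + gr; c <- gx + gc
        if (r >= 1 && r <= h && c >= 1 && c <= w) rgb[r, c, ] <- color
      }
    }
  }
  rgb
}
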