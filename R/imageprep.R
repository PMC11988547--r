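## Tile preparation: grid tiling, blank-tile exclusion, histogram-matching
## stain normalization. Tiles are integer H x W x 3 arrays with 8-bit
## channels; tile grid coordinates are 0-based, row-major, origin at the
## image top-left.

#' Read / write a tile image
#'
#' Thin PNG I/O around the package's tile representation (integer
#' H x W x 3 array, 8-bit channels).
#'
#' @param path file path.
#' @param tile tile array to write.
#' @return `readTile()` returns a tile array; `writeTile()` returns `path`
#'   invisibly.
#' @export
readTile <- function(path) {
  if (!file.exists(path)) ioError(paste("cannot read image:", path))
  px <- png::readPNG(path)
  if (length(dim(px)) == 2L) px <- array(rep(px, 3L), c(dim(px), 3L))
  px <- px[, , 1:3, drop = FALSE]
  arr <- array(as.integer(round(px * 255)), dim(px))
  arr
}

#' @rdname readTile
#' @export
writeTile <- function(tile, path) {
  assertTile(tile)
  png::writePNG(tile / 255, path)
  invisible(path)
}

#' Cut an image into fixed-size tiles
#'
#' Splits a large image (or one level of an image pyramid supplied as a
#' list of arrays, level 0 = highest resolution) into non-overlapping
#' `tileSize` x `tileSize` tiles in row-major grid order. Edge remainders
#' smaller than `tileSize` are dropped so every tile has the uniform size;
#' the 1024-px default matches routine whole-slide tiling practice.
#'
#' @param source an H x W x 3 image array, or a list of such arrays
#'   (pyramid levels, level 0 first).
#' @param tileSize tile side length in pixels.
#' @param level pyramid level to tile (0-based; only 0 is valid for a plain
#'   array source).
#' @param slideId identifier stored with each tile.
#' @return A list of tiles; each element is a list with `pixels`, `slideId`,
#'   `gridX`, `gridY`, `level`.
#' @export
#' @examples
#' img <- array(128L, c(128, 96, 3))
#' length(tileImage(img, 64))  # 1x2 grid -> 2 tiles
tileImage <- function(source, tileSize = 1024L, level = 0L, slideId = "slide") {
  if (is.list(source)) {
    if (level < 0L || level >= length(source)) {
      stopNucleo(sprintf("level %d does not exist (pyramid has %d levels)",
                         level, length(source)), "nucleomicsRangeError")
    }
    img <- source[[level + 1L]]
  } else {
    if (level != 0L) {
      stopNucleo("a plain image has only level 0", "nucleomicsRangeError")
    }
    img <- source
  }
  assertTile(img, "source image")
  tileSize <- as.integer(tileSize)
  h <- dim(img)[1]; w <- dim(img)[2]
  nRows <- h %/% tileSize
  nCols <- w %/% tileSize
  tiles <- vector("list", nRows * nCols)
  k <- 0L
  for (gy in seq_len(nRows) - 1L) {      # row-major: y outer, x inner
    for (gx in seq_len(nCols) - 1L) {
      k <- k + 1L
      rows <- gy * tileSize + seq_len(tileSize)
      cols <- gx * tileSize + seq_len(tileSize)
      tiles[[k]] <- list(pixels = img[rows, cols, , drop = FALSE],
                         slideId = slideId, gridX = gx, gridY = gy,
                         level = level)
    }
  }
  tiles
}

#' Blank-tile rule
#'
#' A tile is blank when more than `blankFraction` of its pixels are
#' near-white (all three channels at or above `whiteCutoff`). This targets
#' unstained slide background; an all-black tile is not blank under this
#' rule. The defaults (220, 0.9) are a documented package choice.
#'
#' @param tile tile array (or a list as returned by [tileImage()]).
#' @param whiteCutoff 8-bit channel cutoff for "near-white".
#' @param blankFraction fraction of near-white pixels above which the tile
#'   is declared blank.
#' @return logical.
#' @export
isBlank <- function(tile, whiteCutoff = 220, blankFraction = 0.9) {
  tile <- asTileArray(tile)
  assertTile(tile)
  nearWhite <- tile[, , 1] >= whiteCutoff &
    tile[, , 2] >= whiteCutoff & tile[, , 3] >= whiteCutoff
  mean(nearWhite) > blankFraction
}

#' Histogram-matching stain normalization
#'
#' Per-channel histogram specification in RGB: each channel of `tile` is
#' remapped so its empirical distribution matches the corresponding channel
#' of the reference image. For 8-bit data the map sends value v to the
#' smallest reference value whose cumulative frequency reaches the tile's
#' cumulative frequency at v. Matching a tile to itself is the identity;
#' the operation is idempotent up to 8-bit quantization.
#'
#' @param tile tile array to normalize.
#' @param reference reference image array (the "optimal staining" image a
#'   pathologist would pick).
#' @return Normalized tile, same shape and 8-bit range as the input.
#' @export
histogramMatch <- function(tile, reference) {
  tile <- asTileArray(tile)
  reference <- asTileArray(reference)
  assertTile(tile); assertTile(reference, "reference")
  out <- tile
  for (ch in 1:3) {
    src <- tile[, , ch]
    ref <- reference[, , ch]
    cdfSrc <- cumsum(tabulate(src + 1L, nbins = 256L)) / length(src)
    cdfRef <- cumsum(tabulate(ref + 1L, nbins = 256L)) / length(ref)
    # map: v -> smallest r with cdfRef[r] >= cdfSrc[v]
    lut <- integer(256L)
    for (v in 1:256) lut[v] <- which(cdfRef >= cdfSrc[v] - 1e-12)[1] - 1L
    out[, , ch] <- lut[src + 1L]
  }
  out
}
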