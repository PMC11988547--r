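## Instance extraction and the adaptive area/compactness quality filter.

#' Extract nucleus instances from a probability map
#'
#' Thresholds a per-pixel foreground probability map at `threshold`, labels
#' 8-connected components and measures each instance (area, outer-boundary
#' perimeter, compactness P^2/A).
#'
#' @param probMap numeric matrix of probabilities in [0, 1] (a binary mask
#'   also works).
#' @param threshold binarization threshold (default 0.5).
#' @param tileId identifier stored in the result.
#' @return A [NucleusSet-class] with unfiltered instances.
#' @export
#' @examples
#' m <- matrix(0, 20, 20); m[3:6, 3:6] <- 1; m[12:18, 10:15] <- 1
#' measures(binarizeAndLabel(m))
binarizeAndLabel <- function(probMap, threshold = 0.5, tileId = "tile") {
  if (min(probMap) < 0 || max(probMap) > 1) {
    validationError("probabilities must lie in [0, 1]")
  }
  labels <- labelConnected(probMap >= threshold)
  meas <- measureInstances(labels)
  new("NucleusSet", tileId = tileId, labels = labels, measures = meas,
      kept = rep(NA, nrow(meas)),
      areaThreshold = NA_real_, compactnessThreshold = NA_real_)
}

#' Adaptive area/compactness quality filter
#'
#' Per-image post-filter on segmented nuclei: Otsu thresholds are computed
#' adaptively on the histograms of the instance areas and compactness
#' values of this tile; instances with area strictly below the area
#' threshold or compactness strictly above the compactness threshold are
#' removed (boundary-equal instances are kept). If a feature is degenerate
#' (all values equal, or fewer than two instances), that criterion is
#' skipped with a message and the other still applies.
#'
#' @param ns a [NucleusSet-class] from [binarizeAndLabel()].
#' @param nBins histogram bins passed to [otsuThreshold()].
#' @return The [NucleusSet-class] with `kept` flags and the two thresholds
#'   filled in (NA for a skipped criterion); `measures(ns)$kept` mirrors
#'   the flags. `keptNuclei(ns)` returns the retained table.
#' @export
filterInstances <- function(ns, nBins = 64L) {
  if (!is(ns, "NucleusSet")) validationError("ns must be a NucleusSet")
  m <- ns@measures
  thr <- function(values, what) {
    tryCatch(otsuThreshold(values, nBins), nucleomicsDegenerateError = function(e) {
      message(sprintf("tile %s: %s criterion skipped (%s)",
                      ns@tileId, what, conditionMessage(e)))
      NA_real_
    })
  }
  if (nrow(m) == 0L) {
    ns@kept <- logical(0)
    ns@measures$kept <- logical(0)
    return(ns)
  }
  aThr <- thr(m$area, "area")
  cThr <- thr(m$compactness, "compactness")
  kept <- rep(TRUE, nrow(m))
  if (!is.na(aThr)) kept <- kept & m$area >= aThr
  if (!is.na(cThr)) kept <- kept & m$compactness <= cThr
  ns@kept <- kept
  ns@measures$kept <- kept
  ns@areaThreshold <- aThr
  ns@compactnessThreshold <- cThr
  ns
}

#' Rasterize polygon annotations to a binary mask
#'
#' Even-odd scanline fill of polygon annotations (LabelMe-style vertex
#' lists) at pixel centers; multiple polygons are unioned. Vertex
#' coordinates are (x = column, y = row) with (1, 1) the center of the
#' top-left pixel.
#'
#' @param polygons list of n x 2 matrices of (x, y) vertices, or the result
#'   of [readLabelMe()].
#' @param height,width output mask size.
#' @return 0/1 integer matrix.
#' @export
rasterizePolygons <- function(polygons, height = 0L, width = 0L) {
  if (is.list(polygons) && !is.null(polygons$polygons)) {
    if (height == 0L) height <- polygons$height
    if (width == 0L) width <- polygons$width
    polygons <- polygons$polygons
  }
  mask <- matrix(0L, height, width)
  cols <- seq_len(width)
  for (poly in polygons) {
    nV <- nrow(poly)
    x1 <- poly[, 1]; y1 <- poly[, 2]
    x2 <- poly[c(2:nV, 1), 1]; y2 <- poly[c(2:nV, 1), 2]
    for (r in seq_len(height)) {
      # half-open rule on y spans handles shared vertices
      crosses <- (y1 <= r & y2 > r) | (y2 <= r & y1 > r)
      if (!any(crosses)) next
      xc <- x1[crosses] + (r - y1[crosses]) *
        (x2[crosses] - x1[crosses]) / (y2[crosses] - y1[crosses])
      inside <- findInterval(cols, sort(xc)) %% 2L == 1L
      mask[r, inside] <- 1L
    }
  }
  mask
}

#' Dice overlap coefficient
#'
#' `2 |X intersect Y| / (|X| + |Y|)` between two binary masks. Two empty
#' masks have Dice 1 by convention.
#'
#' @param a,b binary masks of equal shape.
#' @return numeric in [0, 1].
#' @export
diceCoefficient <- function(a, b) {
  a <- a > 0; b <- b > 0
  if (!identical(dim(a), dim(b))) validationError("mask shapes differ")
  s <- sum(a) + sum(b)
  if (s == 0) return(1)
  2 * sum(a & b) / s
}
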