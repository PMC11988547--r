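## The 20 per-nucleus features: 6 color statistics, 12 morphology
## descriptors, 2 wavelet texture statistics. All variances are population
## variances (divide by N). Moments and Hu invariants are computed on the
## binary silhouette, not intensity; eccentricity comes from the
## moment-equivalent ellipse.

#' Geometric, central and normalized central moments of a silhouette
#'
#' Computes the raw geometric moments \eqn{m_{pq} = \sum_x \sum_y x^p y^q
#' f(x,y)}, the central moments \eqn{\mu_{pq}} about the centroid, and the
#' normalized central moments \eqn{\eta_{pq} = \mu_{pq} / \mu_{00}^\gamma}
#' with \eqn{\gamma = (p+q)/2 + 1}, up to order `maxOrder`. Coordinates are
#' taken relative to the silhouette's bounding box (x along columns, y
#' along rows, 0-based), which makes translation invariance exact in
#' floating point.
#'
#' @param mask binary silhouette matrix (nonzero = foreground).
#' @param maxOrder maximum moment order (default 3, enough for the Hu set).
#' @return List with matrices `m`, `mu`, `eta` (indexed `[p+1, q+1]`) and
#'   the centroid `centroid = c(xbar, ybar)`.
#' @export
momentSet <- function(mask, maxOrder = 3L) {
  idx <- which(mask > 0, arr.ind = TRUE)
  if (nrow(idx) == 0L) validationError("empty silhouette")
  x <- idx[, 2] - min(idx[, 2])       # columns, 0-based in the bounding box
  y <- idx[, 1] - min(idx[, 1])       # rows
  K <- maxOrder + 1L
  m <- matrix(0, K, K)
  for (p in 0:maxOrder) for (q in 0:maxOrder) {
    m[p + 1L, q + 1L] <- sum(x^p * y^q)
  }
  xb <- m[2, 1] / m[1, 1]
  yb <- m[1, 2] / m[1, 1]
  mu <- matrix(0, K, K)
  for (p in 0:maxOrder) for (q in 0:maxOrder) {
    mu[p + 1L, q + 1L] <- sum((x - xb)^p * (y - yb)^q)
  }
  eta <- matrix(0, K, K)
  for (p in 0:maxOrder) for (q in 0:maxOrder) {
    eta[p + 1L, q + 1L] <- mu[p + 1L, q + 1L] / m[1, 1]^((p + q) / 2 + 1)
  }
  list(m = m, mu = mu, eta = eta, centroid = c(xb, yb))
}

#' The seven Hu moment invariants of a binary silhouette
#'
#' Standard Hu invariants from the normalized central moments: invariant to
#' translation exactly, and to rotation and uniform scaling within raster
#' tolerance.
#'
#' @param mask binary silhouette matrix.
#' @return Numeric vector of length 7, named Hu0..Hu6.
#' @export
#' @examples
#' sq <- matrix(0, 9, 9); sq[3:7, 3:7] <- 1
#' huMoments(sq)
huMoments <- function(mask) {
  e <- momentSet(mask)$eta
  n20 <- e[3, 1]; n02 <- e[1, 3]; n11 <- e[2, 2]
  n30 <- e[4, 1]; n03 <- e[1, 4]; n21 <- e[3, 2]; n12 <- e[2, 3]
  s1 <- n30 + n12; s2 <- n21 + n03
  c(Hu0 = n20 + n02,
    Hu1 = (n20 - n02)^2 + 4 * n11^2,
    Hu2 = (n30 - 3 * n12)^2 + (3 * n21 - n03)^2,
    Hu3 = s1^2 + s2^2,
    Hu4 = (n30 - 3 * n12) * s1 * (s1^2 - 3 * s2^2) +
      (3 * n21 - n03) * s2 * (3 * s1^2 - s2^2),
    Hu5 = (n20 - n02) * (s1^2 - s2^2) + 4 * n11 * s1 * s2,
    Hu6 = (3 * n21 - n03) * s1 * (s1^2 - 3 * s2^2) -
      (n30 - 3 * n12) * s2 * (3 * s1^2 - s2^2))
}

#' Shape descriptors of a nucleus silhouette
#'
#' Area A (pixel count), perimeter P (outer-boundary polygon arc length,
#' diagonal steps \eqn{\sqrt 2}), circularity \eqn{4\pi A / P^2},
#' compactness \eqn{P^2 / A} and eccentricity \eqn{E = \sqrt{a^2 - b^2}/a}
#' of the ellipse with the same second central moments as the silhouette
#' (semi-axes \eqn{a \ge b} from the eigenvalues of the second-moment
#' matrix). Holes are filled before measurement. Degenerate silhouettes
#' (single pixels, 1-px lines) get the minor axis clamped at a small
#' positive value and are flagged with attribute `degenerate`.
#'
#' @param mask binary silhouette matrix.
#' @return Named list: A, P, Circularity, Compactness, Eccentric.
#' @export
shapeDescriptors <- function(mask) {
  mask <- fillHoles(matrix(as.integer(mask > 0), nrow(mask), ncol(mask)))
  if (!any(mask > 0)) validationError("empty silhouette")
  A <- sum(mask)
  idx <- which(mask > 0, arr.ind = TRUE)
  y0 <- min(idx[, 1]); x0 <- min(idx[, 2])
  patch <- matrix(0L, max(idx[, 1]) - y0 + 1L, max(idx[, 2]) - x0 + 1L)
  patch[cbind(idx[, 1] - y0 + 1L, idx[, 2] - x0 + 1L)] <- 1L
  P <- traceBoundaryLength(patch)
  mo <- momentSet(mask, maxOrder = 2L)
  mu20 <- mo$mu[3, 1] / A; mu02 <- mo$mu[1, 3] / A; mu11 <- mo$mu[2, 2] / A
  tr <- mu20 + mu02
  disc <- sqrt(max((mu20 - mu02)^2 + 4 * mu11^2, 0))
  l1 <- (tr + disc) / 2
  l2 <- (tr - disc) / 2
  degenerate <- l2 <= 1e-12 || l1 <= 1e-12
  l2 <- max(l2, 1e-12)
  l1 <- max(l1, l2)
  E <- sqrt(max(1 - l2 / l1, 0))
  out <- list(A = A, P = P, Circularity = 4 * pi * A / P^2,
              Compactness = P^2 / A, Eccentric = E)
  attr(out, "degenerate") <- degenerate
  out
}

#' Per-nucleus color statistics
#'
#' Mean and population variance of each RGB channel over the nucleus
#' pixels of a (histogram-matched) tile.
#'
#' @param tile H x W x 3 tile array.
#' @param mask binary matrix selecting the nucleus pixels.
#' @return Named numeric vector: R_average, G_average, B_average, R_var,
#'   G_var, B_var.
#' @export
colorStats <- function(tile, mask) {
  tile <- asTileArray(tile)
  assertTile(tile)
  sel <- mask > 0
  if (!any(sel)) validationError("empty pixel set")
  r <- tile[, , 1][sel]; g <- tile[, , 2][sel]; b <- tile[, , 3][sel]
  c(R_average = mean(r), G_average = mean(g), B_average = mean(b),
    R_var = popVar(r), G_var = popVar(g), B_var = popVar(b))
}

#' Wavelet texture statistics of a nucleus
#'
#' Extracts the instance's bounding-box patch from the grayscale tile
#' (Rec. 601 luma), zeroes non-nucleus pixels, applies a one-level 2-D DWT
#' and returns the mean and population variance of the diagonal detail
#' subband cD.
#'
#' @param tile H x W x 3 tile array.
#' @param mask binary matrix selecting the nucleus pixels.
#' @param wavelet passed to [dwt2()].
#' @return Named numeric vector: cD_average, cD_var.
#' @export
waveletTexture <- function(tile, mask, wavelet = "haar") {
  tile <- asTileArray(tile)
  assertTile(tile)
  sel <- which(mask > 0, arr.ind = TRUE)
  if (nrow(sel) == 0L) validationError("empty pixel set")
  rows <- min(sel[, 1]):max(sel[, 1])
  cols <- min(sel[, 2]):max(sel[, 2])
  patch <- tileToGray(tile)[rows, cols, drop = FALSE]
  patch[mask[rows, cols, drop = FALSE] == 0] <- 0
  cD <- dwt2(patch, wavelet)$cD
  c(cD_average = mean(cD), cD_var = popVar(as.vector(cD)))
}

#' Extract the 20-feature table for a tile's nuclei
#'
#' Computes the full nuclear feature vector for every retained instance of
#' a tile: color statistics on the (histogram-matched) tile, shape
#' descriptors and Hu invariants on the binary silhouette, and wavelet
#' texture on the masked bounding-box patch (per nucleus by default, or
#' once per tile with `scope = "tile"`). A nucleus whose feature
#' computation fails is dropped with a warning, never silently imputed.
#'
#' @param tile H x W x 3 tile array (after stain normalization).
#' @param ns a [NucleusSet-class]; if filtered, only kept instances are
#'   measured.
#' @param patientId,tileId identifiers copied into the output.
#' @param wavelet passed to [dwt2()].
#' @param scope "nucleus" (default) computes cD statistics per nucleus;
#'   "tile" computes them once on the whole grayscale tile.
#' @return data.frame with columns patient_id, tile_id, label and the 20
#'   features of [nuclearFeatureNames()], one row per nucleus.
#' @export
extractFeatures <- function(tile, ns, patientId = NA_character_,
                            tileId = NULL, wavelet = "haar",
                            scope = c("nucleus", "tile")) {
  scope <- match.arg(scope)
  tile <- asTileArray(tile)
  if (!is(ns, "NucleusSet")) validationError("ns must be a NucleusSet")
  if (is.null(tileId)) tileId <- ns@tileId
  m <- ns@measures
  use <- if (anyNA(ns@kept)) seq_len(nrow(m)) else which(ns@kept)
  featNames <- nuclearFeatureNames()
  empty <- as.data.frame(c(
    list(patient_id = character(), tile_id = character(), label = integer()),
    stats::setNames(rep(list(numeric()), length(featNames)), featNames)))
  if (length(use) == 0L) return(empty)

  tileCD <- if (scope == "tile") {
    cD <- dwt2(tileToGray(tile), wavelet)$cD
    c(cD_average = mean(cD), cD_var = popVar(as.vector(cD)))
  } else NULL

  rows <- vector("list", length(use))
  for (k in seq_along(use)) {
    lab <- m$label[use[k]]
    res <- tryCatch({
      mask <- ns@labels == lab
      sil <- fillHoles(matrix(as.integer(mask), nrow(mask), ncol(mask)))
      cs <- colorStats(tile, mask)
      sh <- shapeDescriptors(sil)
      hu <- huMoments(sil)
      wt <- if (scope == "tile") tileCD else waveletTexture(tile, mask, wavelet)
      data.frame(patient_id = patientId, tile_id = tileId, label = lab,
                 R_average = cs[["R_average"]], G_average = cs[["G_average"]],
                 B_average = cs[["B_average"]], R_var = cs[["R_var"]],
                 G_var = cs[["G_var"]], B_var = cs[["B_var"]],
                 Area = sh$A, Perimeter = sh$P,
                 Circularity = sh$Circularity, Compactness = sh$Compactness,
                 Eccentric = sh$Eccentric,
                 Hu0 = hu[["Hu0"]], Hu1 = hu[["Hu1"]], Hu2 = hu[["Hu2"]],
                 Hu3 = hu[["Hu3"]], Hu4 = hu[["Hu4"]], Hu5 = hu[["Hu5"]],
                 Hu6 = hu[["Hu6"]],
                 cD_average = wt[["cD_average"]], cD_var = wt[["cD_var"]],
                 stringsAsFactors = FALSE)
    }, error = function(e) {
      warning(sprintf("nucleus %d dropped: %s", lab, conditionMessage(e)))
      NULL
    })
    rows[[k]] <- res
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) return(empty)
  do.call(rbind, rows)
}
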