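## Connected-component labeling (8-connectivity) and boundary-based
## perimeter measurement. Nucleus blobs are labeled under 8-connectivity;
## the perimeter estimator is the arc length of the outer-boundary pixel
## polygon (unit steps for axis moves, sqrt(2) for diagonal moves),
## obtained by Moore-neighbor tracing. Both choices are fixed so instance
## counts and compactness values are reproducible.

#' Label 8-connected foreground components
#'
#' Two-pass run-based union-find labeling. Components are numbered from 1
#' in row-major order of their first pixel.
#'
#' @param mask logical or 0/1 matrix.
#' @return Integer matrix of labels (0 = background).
#' @export
labelConnected <- function(mask) {
  H <- nrow(mask); W <- ncol(mask)
  fg <- mask > 0
  labels <- matrix(0L, H, W)
  parent <- integer(0)
  findRoot <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  prevRuns <- NULL  # matrix: start, end, label (of the previous row)
  for (y in seq_len(H)) {
    row <- fg[y, ]
    if (!any(row)) { prevRuns <- NULL; next }
    r <- rle(row)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    runs <- cbind(starts[r$values], ends[r$values], 0L)
    for (k in seq_len(nrow(runs))) {
      s <- runs[k, 1]; e <- runs[k, 2]
      lab <- 0L
      if (!is.null(prevRuns)) {
        # 8-connectivity: previous-row runs overlapping [s-1, e+1]
        hits <- which(prevRuns[, 1] <= e + 1L & prevRuns[, 2] >= s - 1L)
        for (h in hits) {
          r2 <- findRoot(prevRuns[h, 3])
          if (lab == 0L) {
            lab <- r2
          } else if (r2 != lab) {
            lo <- min(lab, r2)
            parent[max(lab, r2)] <- lo
            lab <- lo
          }
        }
      }
      if (lab == 0L) {
        parent[length(parent) + 1L] <- length(parent) + 1L
        lab <- length(parent)
      }
      runs[k, 3] <- lab
      labels[y, s:e] <- lab
    }
    prevRuns <- runs
  }
  if (!length(parent)) return(labels)
  roots <- vapply(seq_along(parent), findRoot, integer(1))
  # renumber roots by first appearance in row-major pixel order
  flat <- as.vector(t(labels))        # row-major scan
  flatRoots <- roots[flat[flat > 0L]]
  u <- unique(flatRoots)
  newId <- integer(length(parent))
  newId[u] <- seq_along(u)
  relab <- labels
  relab[labels > 0L] <- newId[roots[labels[labels > 0L]]]
  relab
}

# Moore-neighbor boundary trace of a single-instance mask patch; returns the
# arc length of the closed outer boundary through pixel centers. Degenerate
# single-pixel instances get the documented minimum length 1.
traceBoundaryLength <- function(patch) {
  H <- nrow(patch); W <- ncol(patch)
  if (sum(patch) == 1L) return(1)
  # pad so neighbor lookups never leave the matrix
  p <- matrix(FALSE, H + 2L, W + 2L)
  p[2:(H + 1L), 2:(W + 1L)] <- patch > 0
  # first foreground pixel in row-major order
  start <- NULL
  for (y in 2:(H + 1L)) {
    x <- which(p[y, ])[1]
    if (!is.na(x)) { start <- c(y, x); break }
  }
  # clockwise Moore neighborhood starting west
  off <- rbind(c(0, -1), c(-1, -1), c(-1, 0), c(-1, 1),
               c(0, 1), c(1, 1), c(1, 0), c(1, -1))
  cur <- start
  back <- start + off[1, ]           # came from the west
  firstMove <- NULL
  len <- 0
  repeat {
    d <- back - cur
    i <- which(off[, 1] == d[1] & off[, 2] == d[2])
    nxt <- NULL
    for (j in (i + seq_len(8L))) {
      jj <- ((j - 1L) %% 8L) + 1L
      cand <- cur + off[jj, ]
      if (p[cand[1], cand[2]]) {
        prev <- ((j - 2L) %% 8L) + 1L
        nxt <- cand
        back <- cur + off[prev, ]
        break
      }
    }
    if (is.null(nxt)) return(1)       # isolated pixel (shouldn't happen here)
    step <- sqrt(sum((nxt - cur)^2))
    move <- c(cur, nxt)
    if (is.null(firstMove)) {
      firstMove <- move
    } else if (all(move == firstMove)) {
      break                           # boundary closed: same edge re-traversed
    }
    len <- len + step
    cur <- nxt
    if (len > 8 * (H + W) * 2) break  # safety net; cannot trigger on valid masks
  }
  len
}

# Per-instance measurements from a label matrix: area A (pixel count),
# perimeter P (outer-boundary arc length, holes filled first), compactness
# C = P^2 / A.
measureInstances <- function(labels) {
  n <- max(labels)
  if (n == 0L) {
    return(data.frame(label = integer(), area = numeric(),
                      perimeter = numeric(), compactness = numeric()))
  }
  out <- vector("list", n)
  for (lab in seq_len(n)) {
    idx <- which(labels == lab, arr.ind = TRUE)
    A <- nrow(idx)
    y0 <- min(idx[, 1]); y1 <- max(idx[, 1])
    x0 <- min(idx[, 2]); x1 <- max(idx[, 2])
    patch <- matrix(0L, y1 - y0 + 1L, x1 - x0 + 1L)
    patch[cbind(idx[, 1] - y0 + 1L, idx[, 2] - x0 + 1L)] <- 1L
    patch <- fillHoles(patch)
    P <- traceBoundaryLength(patch)
    out[[lab]] <- data.frame(label = lab, area = A, perimeter = P,
                             compactness = P^2 / A)
  }
  do.call(rbind, out)
}

# Fill interior holes of a binary patch (4-connected background flood fill
# from the border), via EBImage.
fillHoles <- function(patch) {
  f <- EBImage::fillHull(patch)
  matrix(as.integer(f > 0), nrow(patch), ncol(patch))
}
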