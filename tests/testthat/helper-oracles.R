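# Independent brute-force oracles used to verify the package's
# implementations. These are deliberately naive (loops, direct formula
# evaluation) and share no code with the functions they check.

# Exhaustive Otsu: maximize between-class variance over every bin edge.
otsuBrute <- function(values, nBins = 64L) {
  lo <- min(values); hi <- max(values)
  width <- (hi - lo) / nBins
  idx <- pmin(floor((values - lo) / width) + 1L, nBins)
  counts <- tabulate(idx, nbins = nBins)
  centers <- lo + (seq_len(nBins) - 0.5) * width
  best <- -Inf; bestT <- NA
  for (t in 1:(nBins - 1L)) {
    n0 <- sum(counts[1:t]); n1 <- sum(counts) - n0
    if (n0 == 0 || n1 == 0) next
    mu0 <- sum(counts[1:t] * centers[1:t]) / n0
    mu1 <- sum(counts[(t + 1):nBins] * centers[(t + 1):nBins]) / n1
    bc <- (n0 / sum(counts)) * (n1 / sum(counts)) * (mu0 - mu1)^2
    if (bc > best + 1e-15) { best <- bc; bestT <- lo + t * width }
  }
  bestT
}

# Naive double-loop evaluation of the moment equations and Hu invariants.
huBrute <- function(mask) {
  idx <- which(mask > 0, arr.ind = TRUE)
  xs <- idx[, 2] - min(idx[, 2]); ys <- idx[, 1] - min(idx[, 1])
  m <- function(p, q) {
    terms <- numeric(length(xs))
    for (i in seq_along(xs)) terms[i] <- xs[i]^p * ys[i]^q
    sum(terms)
  }
  xb <- m(1, 0) / m(0, 0); yb <- m(0, 1) / m(0, 0)
  mu <- function(p, q) {
    terms <- numeric(length(xs))
    for (i in seq_along(xs)) terms[i] <- (xs[i] - xb)^p * (ys[i] - yb)^q
    sum(terms)
  }
  eta <- function(p, q) mu(p, q) / m(0, 0)^((p + q) / 2 + 1)
  n20 <- eta(2, 0); n02 <- eta(0, 2); n11 <- eta(1, 1)
  n30 <- eta(3, 0); n03 <- eta(0, 3); n21 <- eta(2, 1); n12 <- eta(1, 2)
  c((n20 + n02),
    (n20 - n02)^2 + 4 * n11^2,
    (n30 - 3 * n12)^2 + (3 * n21 - n03)^2,
    (n30 + n12)^2 + (n21 + n03)^2,
    (n30 - 3 * n12) * (n30 + n12) * ((n30 + n12)^2 - 3 * (n21 + n03)^2) +
      (3 * n21 - n03) * (n21 + n03) * (3 * (n30 + n12)^2 - (n21 + n03)^2),
    (n20 - n02) * ((n30 + n12)^2 - (n21 + n03)^2) +
      4 * n11 * (n30 + n12) * (n21 + n03),
    (3 * n21 - n03) * (n30 + n12) * ((n30 + n12)^2 - 3 * (n21 + n03)^2) -
      (n30 - 3 * n12) * (n21 + n03) * (3 * (n30 + n12)^2 - (n21 + n03)^2))
}

# Direct separable one-level Haar transform by explicit summation.
dwt2Brute <- function(x) {
  g <- c(1, 1) / sqrt(2); h <- c(1, -1) / sqrt(2)
  H <- nrow(x); W <- ncol(x)
  Ah <- matrix(0, H, W %/% 2); Dh <- matrix(0, H, W %/% 2)
  for (i in 1:H) for (j in 1:(W %/% 2)) {
    Ah[i, j] <- g[1] * x[i, 2 * j - 1] + g[2] * x[i, 2 * j]
    Dh[i, j] <- h[1] * x[i, 2 * j - 1] + h[2] * x[i, 2 * j]
  }
  cD <- matrix(0, H %/% 2, W %/% 2)
  for (i in 1:(H %/% 2)) for (j in 1:(W %/% 2)) {
    cD[i, j] <- h[1] * Dh[2 * i - 1, j] + h[2] * Dh[2 * i, j]
  }
  cD
}

# Loop-summation Pearson r plus a p-value from numeric integration of the
# t density.
pearsonBrute <- function(x, y) {
  n <- length(x)
  xb <- sum(x) / n; yb <- sum(y) / n
  num <- 0; dx <- 0; dy <- 0
  for (i in 1:n) {
    num <- num + (x[i] - xb) * (y[i] - yb)
    dx <- dx + (x[i] - xb)^2
    dy <- dy + (y[i] - yb)^2
  }
  r <- num / sqrt(dx * dy)
  tstat <- r * sqrt((n - 2) / (1 - r^2))
  dens <- function(u) {
    gamma((n - 1) / 2) / (sqrt((n - 2) * pi) * gamma((n - 2) / 2)) *
      (1 + u^2 / (n - 2))^(-(n - 1) / 2)
  }
  p <- 2 * stats::integrate(dens, abs(tstat), Inf, rel.tol = 1e-10)$value
  list(r = r, p = p)
}

# Rank-statistic AUC: pairwise positive-vs-negative comparisons, ties 1/2.
aucMannWhitney <- function(yTrue, scores) {
  pos <- scores[yTrue == max(yTrue)]
  neg <- scores[yTrue != max(yTrue)]
  s <- 0
  for (p in pos) for (q in neg) {
    s <- s + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  s / (length(pos) * length(neg))
}

# Rasterize an axis-rotated ellipse the same way a continuous inclusion
# test would (pixel centers), independent of the renderer's code path.
ellipseMask <- function(h, w, cx, cy, a, b, theta = 0) {
  m <- matrix(0L, h, w)
  for (r in 1:h) for (cc in 1:w) {
    dx <- cc - cx; dy <- r - cy
    u <- (dx * cos(theta) + dy * sin(theta)) / a
    v <- (-dx * sin(theta) + dy * cos(theta)) / b
    if (u * u + v * v <= 1) m[r, cc] <- 1L
  }
  m
}

# Small deterministic RGB tile with the given base color.
flatTile <- function(h, w, rgb = c(128, 128, 128)) {
  arr <- array(0L, c(h, w, 3))
  for (ch in 1:3) arr[, , ch] <- as.integer(rgb[ch])
  arr
}

smallCohort <- function(n1 = 4, n2 = 4, seed = 5, tileSize = 64,
                        effect = c(area = 0.8, eccentricity = 0.4,
                                   color = 6, expression = 1.0), ...) {
  generateCohort(cohortSpec(nPatientsClass1 = n1, nPatientsClass2 = n2,
                            tileSize = tileSize, classEffect = effect,
                            seed = seed, ...))
}
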