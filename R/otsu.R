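#' Otsu threshold of a continuous feature sample
#'
#' Computes the classic between-class-variance-maximizing threshold on the
#' histogram of `values`, binned into `nBins` equal-width bins spanning the
#' observed range. The discriminative criterion is the usual one: a cut
#' between bins splits the histogram into two classes with weights
#' \eqn{w_0, w_1} and means \eqn{\mu_0, \mu_1}; the returned threshold is
#' the bin edge maximizing \eqn{w_0 w_1 (\mu_0 - \mu_1)^2}, which is
#' equivalent to minimizing the within-class variance. Used as the adaptive
#' per-image cut on nucleus area and compactness in [filterInstances()].
#'
#' Ties on the criterion are broken toward the smallest threshold.
#'
#' @param values numeric vector with at least two distinct values.
#' @param nBins number of equal-width histogram bins (default 64).
#' @return The selected threshold (a bin edge, on the scale of `values`).
#' @seealso [filterInstances()]
#' @export
#' @examples
#' otsuThreshold(c(rnorm(50, 2), rnorm(50, 10)))
otsuThreshold <- function(values, nBins = 64L) {
  values <- as.numeric(values)
  if (length(values) < 2L || anyNA(values)) {
    degenerateError("otsuThreshold() needs >= 2 finite values")
  }
  lo <- min(values); hi <- max(values)
  if (lo == hi) {
    degenerateError("all values identical; no threshold separates them")
  }
  nBins <- as.integer(nBins)
  width <- (hi - lo) / nBins
  # right-closed bins; the max lands in the last bin
  idx <- pmin(floor((values - lo) / width) + 1L, nBins)
  counts <- tabulate(idx, nbins = nBins)
  centers <- lo + (seq_len(nBins) - 0.5) * width

  n <- length(values)
  cumN <- cumsum(counts)
  cumS <- cumsum(counts * centers)
  t <- seq_len(nBins - 1L)            # cut after bin t
  w0 <- cumN[t] / n
  w1 <- 1 - w0
  valid <- w0 > 0 & w1 > 0
  mu0 <- cumS[t] / cumN[t]
  mu1 <- (cumS[nBins] - cumS[t]) / (n - cumN[t])
  crit <- ifelse(valid, w0 * w1 * (mu0 - mu1)^2, -Inf)
  best <- which.max(crit)             # smallest argmax on ties
  lo + best * width
}
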