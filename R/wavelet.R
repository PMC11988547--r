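## Single-level separable 2-D discrete wavelet transform. The texture
## features use only one level and the diagonal detail subband cD, so the
## transform is implemented directly: rows are filtered with the low-pass
## filter g and high-pass filter h and dyadically downsampled, then the
## same is applied to columns. Odd-length inputs are extended by repeating
## the final sample.

dwtFilters <- function(wavelet) {
  if (is.list(wavelet)) {
    stopifnot(!is.null(wavelet$g), !is.null(wavelet$h))
    return(wavelet)
  }
  switch(tolower(wavelet),
    haar = ,
    db1 = list(g = c(1, 1) / sqrt(2), h = c(1, -1) / sqrt(2)),
    configError(paste("unknown wavelet:", wavelet))
  )
}

# 1-D analysis step: out[j] = sum_k f[k] * s[2j - 2 + k]
dwt1 <- function(s, f) {
  L <- length(f)
  if (length(s) %% 2L == 1L) s <- c(s, s[length(s)])
  n <- length(s)
  if (L > 2L) s <- c(s, rep(s[n], L - 2L))
  half <- n %/% 2L
  out <- numeric(half)
  for (j in seq_len(half)) {
    out[j] <- sum(f * s[2L * j - 2L + seq_len(L)])
  }
  out
}

#' Single-level 2-D discrete wavelet transform
#'
#' Separable analysis transform: rows then columns, each filtered with the
#' low-pass (g) and high-pass (h) filters and downsampled by 2, yielding
#' the approximation subband cA and the horizontal/vertical/diagonal detail
#' subbands cH, cV, cD. The diagonal band cD (high-pass in both directions)
#' is the texture carrier used by [waveletTexture()].
#'
#' @param x numeric matrix (grayscale patch).
#' @param wavelet "haar" (= "db1"), or a list with elements `g` and `h`.
#' @return List of the four subband matrices cA, cH, cV, cD.
#' @export
#' @examples
#' dwt2(matrix(c(1, 0, 0, 1), 2, 2, byrow = TRUE))$cD  # = 1
dwt2 <- function(x, wavelet = "haar") {
  if (!is.matrix(x)) x <- as.matrix(x)
  flt <- dwtFilters(wavelet)
  if (min(dim(x)) < 2L) {
    validationError("patch must be at least 2 x 2 for a one-level transform")
  }
  rowStep <- function(m, f) {
    r <- apply(m, 1L, dwt1, f = f)
    if (is.matrix(r)) t(r) else matrix(r, ncol = 1L)
  }
  colStep <- function(m, f) {
    r <- apply(m, 2L, dwt1, f = f)
    if (is.matrix(r)) r else matrix(r, nrow = 1L)
  }
  Ah <- rowStep(x, flt$g)   # row low-pass
  Dh <- rowStep(x, flt$h)   # row high-pass
  list(cA = colStep(Ah, flt$g),
       cH = colStep(Ah, flt$h),
       cV = colStep(Dh, flt$g),
       cD = colStep(Dh, flt$h))
}
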