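## Pearson-correlation factor screening: every factor is correlated with
## the task label; factors with |r| > 0.05 and p < 0.05 are retained.

#' Pearson correlation with a two-sided p-value
#'
#' Wraps the standard product-moment test: r is the Pearson coefficient
#' and p the two-sided p-value of the t statistic
#' \eqn{r \sqrt{(n-2)/(1-r^2)}} on n - 2 degrees of freedom. A constant
#' vector has no defined correlation and raises a degenerate-input error.
#'
#' @param x,y numeric vectors of equal length (n >= 3).
#' @return List with elements `r` and `p`.
#' @export
#' @examples
#' pearsonTest(1:10, (1:10) * 2 + rnorm(10))
pearsonTest <- function(x, y) {
  if (length(x) != length(y)) validationError("x and y lengths differ")
  if (length(x) < 3L) validationError("need n >= 3")
  if (sd(x) == 0 || sd(y) == 0) {
    degenerateError("correlation undefined for a constant vector")
  }
  ct <- cor.test(x, y, method = "pearson", alternative = "two.sided")
  list(r = unname(ct$estimate), p = ct$p.value)
}

#' Screen factors by correlation with the task label
#'
#' Computes the Pearson correlation of every design-matrix factor with the
#' numeric task label on the training partition (avoiding leakage into the
#' held-out sets) and applies the retention rule |r| > 0.05 and p < 0.05.
#' Constant (degenerate) factors are reported as non-retained with a flag,
#' never dropped silently. The factor-factor correlation matrix is
#' attached for heatmap export, with |r| > 0.8 pairs flagged.
#'
#' @param dataset an [AssembledDataset-class], or a numeric design matrix.
#' @param label numeric label vector (defaults to the dataset's task label).
#' @param subset partition screened (default "train"; NULL = all rows).
#' @param aggregate "nucleus" screens per-nucleus rows (default);
#'   "patient" first averages rows within patient.
#' @param rCut,pCut retention rule cutoffs.
#' @param highCorr threshold flagging strongly related factor pairs.
#' @return data.frame with columns factor, r, p, retained, degenerate and
#'   highCorrWith (comma-separated partners with |r| > `highCorr`);
#'   attributes `correlationMatrix` (factor x factor r values) and
#'   `retainedFactors`.
#' @export
screenFactors <- function(dataset, label = NULL, subset = "train",
                          aggregate = c("nucleus", "patient"),
                          rCut = 0.05, pCut = 0.05, highCorr = 0.8) {
  aggregate <- match.arg(aggregate)
  if (is(dataset, "AssembledDataset")) {
    X <- designMatrix(dataset, subset = subset)
    if (is.null(label)) label <- taskLabels(dataset, subset = subset)
    pid <- dataset@data$patient_id
    if (!is.null(subset)) {
      pid <- pid[dataset@partition[pid] == subset]
    }
  } else {
    X <- as.matrix(dataset)
    if (is.null(label)) validationError("label is required for a plain matrix")
    pid <- NULL
  }
  if (aggregate == "patient") {
    if (is.null(pid)) validationError("patient aggregation needs an AssembledDataset")
    X <- apply(X, 2L, function(col) tapply(col, pid, mean))
    label <- as.numeric(tapply(label, pid, function(v) v[1]))
  }
  label <- as.numeric(label)

  res <- lapply(colnames(X), function(f) {
    out <- tryCatch(pearsonTest(X[, f], label),
                    nucleomicsDegenerateError = function(e) NULL)
    if (is.null(out)) {
      data.frame(factor = f, r = NA_real_, p = NA_real_,
                 retained = FALSE, degenerate = TRUE,
                 stringsAsFactors = FALSE)
    } else {
      data.frame(factor = f, r = out$r, p = out$p,
                 retained = abs(out$r) > rCut && out$p < pCut,
                 degenerate = FALSE, stringsAsFactors = FALSE)
    }
  })
  res <- do.call(rbind, res)

  ok <- !res$degenerate
  cm <- matrix(NA_real_, ncol(X), ncol(X),
               dimnames = list(colnames(X), colnames(X)))
  if (any(ok)) cm[ok, ok] <- stats::cor(X[, ok, drop = FALSE])
  res$highCorrWith <- vapply(seq_len(nrow(res)), function(i) {
    if (!ok[i]) return("")
    partners <- colnames(cm)[ok & abs(cm[i, ]) > highCorr &
                               colnames(cm) != res$factor[i]]
    paste(partners, collapse = ",")
  }, character(1))

  attr(res, "correlationMatrix") <- cm
  attr(res, "retainedFactors") <- res$factor[res$retained]
  res
}

#' Write the screening report and correlation matrix
#'
#' @param screen result of [screenFactors()].
#' @param dir output directory.
#' @param heatmap also render a PNG heatmap (needs the pheatmap package).
#' @return Invisibly, the paths written.
#' @export
writeScreenReport <- function(screen, dir, heatmap = FALSE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p1 <- file.path(dir, "screening.csv")
  utils::write.csv(screen, p1, row.names = FALSE)
  p2 <- file.path(dir, "correlation_matrix.csv")
  utils::write.csv(attr(screen, "correlationMatrix"), p2)
  paths <- c(p1, p2)
  if (heatmap && requireNamespace("pheatmap", quietly = TRUE)) {
    p3 <- file.path(dir, "correlation_heatmap.png")
    cm <- attr(screen, "correlationMatrix")
    cm[is.na(cm)] <- 0
    grDevices::png(p3, width = 1200, height = 1200)
    pheatmap::pheatmap(cm, cluster_rows = FALSE, cluster_cols = FALSE,
                       display_numbers = matrix(
                         ifelse(abs(cm) > 0.8 & row(cm) != col(cm), "+", ""),
                         nrow(cm)))
    grDevices::dev.off()
    paths <- c(paths, p3)
  }
  invisible(paths)
}
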