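## Compact U-shaped encoder-decoder segmenter, implemented natively with
## im2col 3x3 convolutions, 2x2 mean pooling, nearest-neighbor upsampling,
## skip concatenation, a 1x1 sigmoid output head, and Adam on pixel-wise
## binary cross-entropy. Deliberately small so CPU training on synthetic
## tiles finishes in minutes; depth and width are configurable.

## -- convolution primitives --------------------------------------------------

# H x W x C feature map -> (H*W) x (9C) patch matrix, zero padding 1.
im2col3 <- function(x) {
  H <- dim(x)[1]; W <- dim(x)[2]; C <- dim(x)[3]
  xp <- array(0, c(H + 2L, W + 2L, C))
  xp[2:(H + 1L), 2:(W + 1L), ] <- x
  cols <- matrix(0, H * W, 9L * C)
  k <- 0L
  for (c in seq_len(C)) for (dx in 0:2) for (dy in 0:2) {
    k <- k + 1L
    cols[, k] <- as.vector(xp[dy + seq_len(H), dx + seq_len(W), c])
  }
  cols
}

# transpose of im2col3: scatter-add patch-matrix gradients back to H x W x C
col2im3 <- function(dCols, H, W, C) {
  dxp <- array(0, c(H + 2L, W + 2L, C))
  k <- 0L
  for (c in seq_len(C)) for (dx in 0:2) for (dy in 0:2) {
    k <- k + 1L
    dxp[dy + seq_len(H), dx + seq_len(W), c] <-
      dxp[dy + seq_len(H), dx + seq_len(W), c] + matrix(dCols[, k], H, W)
  }
  dxp[2:(H + 1L), 2:(W + 1L), , drop = FALSE]
}

convForward <- function(x, W, b) {
  H <- dim(x)[1]; Wd <- dim(x)[2]
  M <- im2col3(x)
  out <- sweep(M %*% W, 2L, b, "+")
  list(out = array(out, c(H, Wd, ncol(W))), M = M)
}

convBackward <- function(cache, x, W, dOut) {
  H <- dim(x)[1]; Wd <- dim(x)[2]; Cout <- ncol(W)
  dMat <- matrix(dOut, H * Wd, Cout)
  list(dW = crossprod(cache$M, dMat),
       db = colSums(dMat),
       dX = col2im3(dMat %*% t(W), H, Wd, dim(x)[3]))
}

meanPool2 <- function(x) {
  H <- dim(x)[1]; W <- dim(x)[2]
  o1 <- seq(1L, H, 2L); o2 <- seq(1L, W, 2L)
  (x[o1, o2, , drop = FALSE] + x[o1 + 1L, o2, , drop = FALSE] +
     x[o1, o2 + 1L, , drop = FALSE] + x[o1 + 1L, o2 + 1L, , drop = FALSE]) / 4
}

meanPool2Back <- function(dOut) {
  dOut[rep(seq_len(dim(dOut)[1]), each = 2L),
       rep(seq_len(dim(dOut)[2]), each = 2L), , drop = FALSE] / 4
}

upsample2 <- function(x) {
  x[rep(seq_len(dim(x)[1]), each = 2L),
    rep(seq_len(dim(x)[2]), each = 2L), , drop = FALSE]
}

upsample2Back <- function(dOut) {
  4 * meanPool2(dOut)
}

## -- model -------------------------------------------------------------------

#' Segmenter training configuration
#'
#' @param depth number of resolution levels (depth - 1 poolings).
#' @param baseChannels channels of the first encoder level; level d uses
#'   `baseChannels * 2^(d-1)`.
#' @param epochs training epochs.
#' @param lr Adam learning rate.
#' @param batchSize tiles per gradient step.
#' @param seed RNG seed controlling initialization and shuffling.
#' @return A named list.
#' @export
segmenterConfig <- function(depth = 4L, baseChannels = 16L, epochs = 30L,
                            lr = 0.01, batchSize = 4L, seed = 1L) {
  list(depth = as.integer(depth), baseChannels = as.integer(baseChannels),
       epochs = as.integer(epochs), lr = lr,
       batchSize = as.integer(batchSize), seed = as.integer(seed))
}

unetInit <- function(config) {
  D <- config$depth; base <- config$baseChannels
  ch <- base * 2^(seq_len(D) - 1L)
  he <- function(cin, cout) {
    list(W = matrix(rnorm(9 * cin * cout, 0, sqrt(2 / (9 * cin))),
                    9 * cin, cout),
         b = numeric(cout))
  }
  enc <- vector("list", D)
  prev <- 3L
  for (d in seq_len(D)) {
    enc[[d]] <- he(prev, ch[d])
    prev <- ch[d]
  }
  dec <- vector("list", max(D - 1L, 0L))
  for (d in rev(seq_len(D - 1L))) {
    dec[[d]] <- he(ch[d] + ch[d + 1L], ch[d])
  }
  out <- list(W = matrix(rnorm(ch[1], 0, sqrt(2 / ch[1])), ch[1], 1L),
              b = 0)
  list(enc = enc, dec = dec, out = out, channels = ch)
}

unetForward <- function(weights, x, keepCache = FALSE) {
  D <- length(weights$enc)
  encAct <- vector("list", D)
  caches <- list(enc = vector("list", D), dec = vector("list", D - 1L))
  cur <- x
  for (d in seq_len(D)) {
    cv <- convForward(cur, weights$enc[[d]]$W, weights$enc[[d]]$b)
    act <- pmax(cv$out, 0)
    caches$enc[[d]] <- list(M = cv$M, pre = cv$out, input = cur)
    encAct[[d]] <- act
    if (d < D) cur <- meanPool2(act) else cur <- act
  }
  for (d in rev(seq_len(D - 1L))) {
    up <- upsample2(cur)
    cat3 <- array(c(encAct[[d]], up),
                  c(dim(up)[1], dim(up)[2], dim(encAct[[d]])[3] + dim(up)[3]))
    cv <- convForward(cat3, weights$dec[[d]]$W, weights$dec[[d]]$b)
    act <- pmax(cv$out, 0)
    caches$dec[[d]] <- list(M = cv$M, pre = cv$out, input = cat3,
                            skipC = dim(encAct[[d]])[3])
    cur <- act
  }
  H <- dim(cur)[1]; W <- dim(cur)[2]
  logits <- matrix(matrix(cur, H * W, dim(cur)[3]) %*% weights$out$W +
                     weights$out$b, H, W)
  prob <- 1 / (1 + exp(-logits))
  res <- list(prob = prob, final = cur)
  if (keepCache) res$caches <- caches
  res
}

# gradients of mean BCE loss wrt every weight tensor, one tile
unetBackward <- function(weights, x, y, fwd) {
  D <- length(weights$enc)
  H <- dim(fwd$prob)[1]; W <- dim(fwd$prob)[2]
  n <- H * W
  grads <- list(enc = vector("list", D), dec = vector("list", D - 1L))
  dLogit <- (fwd$prob - y) / n
  finalMat <- matrix(fwd$final, n, dim(fwd$final)[3])
  grads$out <- list(W = crossprod(finalMat, as.vector(dLogit)),
                    db = sum(dLogit))
  dCur <- array(as.vector(dLogit) %o% as.vector(weights$out$W),
                c(H, W, nrow(weights$out$W)))
  for (d in seq_len(D - 1L)) {
    cache <- fwd$caches$dec[[d]]
    dPre <- dCur * (cache$pre > 0)
    g <- convBackward(cache, cache$input, weights$dec[[d]]$W, dPre)
    grads$dec[[d]] <- list(W = g$dW, db = g$db)
    sk <- cache$skipC
    grads$skip <- grads$skip %||% vector("list", D)
    grads$skip[[d]] <- g$dX[, , seq_len(sk), drop = FALSE]
    dCur <- upsample2Back(g$dX[, , (sk + 1L):dim(g$dX)[3], drop = FALSE])
  }
  # dCur now flows into the deepest encoder activation
  for (d in rev(seq_len(D))) {
    cache <- fwd$caches$enc[[d]]
    dAct <- if (d == D) dCur else meanPool2Back(dCur)
    if (d < D && !is.null(grads$skip[[d]])) {
      dAct <- dAct + grads$skip[[d]]
    }
    dPre <- dAct * (cache$pre > 0)
    g <- convBackward(cache, cache$input, weights$enc[[d]]$W, dPre)
    grads$enc[[d]] <- list(W = g$dW, db = g$db)
    dCur <- g$dX
  }
  grads$skip <- NULL
  grads
}

## flatten/apply helpers so Adam state is a flat list of tensors
collectTensors <- function(w) {
  out <- list()
  for (d in seq_along(w$enc)) {
    out[[paste0("encW", d)]] <- w$enc[[d]]$W
    out[[paste0("encb", d)]] <- w$enc[[d]]$b
  }
  for (d in seq_along(w$dec)) {
    out[[paste0("decW", d)]] <- w$dec[[d]]$W
    out[[paste0("decb", d)]] <- w$dec[[d]]$b
  }
  out$outW <- w$out$W; out$outb <- w$out$b
  out
}

gradTensors <- function(g) {
  out <- list()
  for (d in seq_along(g$enc)) {
    out[[paste0("encW", d)]] <- g$enc[[d]]$W
    out[[paste0("encb", d)]] <- g$enc[[d]]$db
  }
  for (d in seq_along(g$dec)) {
    out[[paste0("decW", d)]] <- g$dec[[d]]$W
    out[[paste0("decb", d)]] <- g$dec[[d]]$db
  }
  out$outW <- g$out$W; out$outb <- g$out$db
  out
}

restoreTensors <- function(w, flat) {
  for (d in seq_along(w$enc)) {
    w$enc[[d]]$W <- flat[[paste0("encW", d)]]
    w$enc[[d]]$b <- flat[[paste0("encb", d)]]
  }
  for (d in seq_along(w$dec)) {
    w$dec[[d]]$W <- flat[[paste0("decW", d)]]
    w$dec[[d]]$b <- flat[[paste0("decb", d)]]
  }
  w$out$W <- flat$outW; w$out$b <- flat$outb
  w
}

## -- public API --------------------------------------------------------------

.checkPair <- function(tile, mask, depth) {
  tile <- asTileArray(tile)
  assertTile(tile)
  if (!identical(dim(tile)[1:2], dim(mask))) {
    validationError("tile and mask shapes differ")
  }
  div <- 2^(depth - 1L)
  if (any(dim(mask) %% div != 0)) {
    validationError(sprintf(
      "tile sides must be multiples of %d for depth %d", div, depth))
  }
  tile
}

#' Train the U-shaped nucleus segmenter
#'
#' Trains the encoder-decoder on (tile, mask) pairs with Adam on pixel-wise
#' binary cross-entropy. Training is deterministic given `config$seed`; the
#' mean loss of every epoch is recorded in `lossHistory()`.
#'
#' @param tiles list of H x W x 3 tiles (8-bit arrays, or [renderTile()]
#'   results).
#' @param masks list of matching 0/1 mask matrices (omit when `tiles` are
#'   [renderTile()] results, which carry their masks).
#' @param config a [segmenterConfig()].
#' @return A [UNetSegmenter-class].
#' @seealso [predictSegmenter()], [saveSegmenter()]
#' @export
trainSegmenter <- function(tiles, masks = NULL, config = segmenterConfig()) {
  if (length(tiles) < 1L) validationError("need at least one training pair")
  if (is.null(masks) && !is.null(tiles[[1]]$mask)) {
    masks <- lapply(tiles, `[[`, "mask")
  }
  if (length(masks) != length(tiles)) {
    validationError("tiles and masks differ in length")
  }
  xs <- vector("list", length(tiles))
  for (i in seq_along(tiles)) {
    xs[[i]] <- .checkPair(tiles[[i]], masks[[i]], config$depth) / 255
  }
  withSeed(config$seed, {
    weights <- unetInit(config)
    mState <- vState <- lapply(collectTensors(weights), function(t) t * 0)
    beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
    step <- 0L
    lossHist <- numeric(config$epochs)
    nT <- length(xs)
    for (ep in seq_len(config$epochs)) {
      ord <- sample.int(nT)
      epLoss <- 0
      for (bStart in seq(1L, nT, config$batchSize)) {
        batch <- ord[bStart:min(bStart + config$batchSize - 1L, nT)]
        acc <- NULL
        for (i in batch) {
          fwd <- unetForward(weights, xs[[i]], keepCache = TRUE)
          p <- pmin(pmax(fwd$prob, 1e-7), 1 - 1e-7)
          y <- masks[[i]]
          epLoss <- epLoss - mean(y * log(p) + (1 - y) * log(1 - p))
          g <- gradTensors(unetBackward(weights, xs[[i]], y, fwd))
          acc <- if (is.null(acc)) g else Map(`+`, acc, g)
        }
        acc <- lapply(acc, `/`, length(batch))
        step <- step + 1L
        flat <- collectTensors(weights)
        for (nm in names(flat)) {
          mState[[nm]] <- beta1 * mState[[nm]] + (1 - beta1) * acc[[nm]]
          vState[[nm]] <- beta2 * vState[[nm]] + (1 - beta2) * acc[[nm]]^2
          mHat <- mState[[nm]] / (1 - beta1^step)
          vHat <- vState[[nm]] / (1 - beta2^step)
          flat[[nm]] <- flat[[nm]] - config$lr * mHat / (sqrt(vHat) + eps)
        }
        weights <- restoreTensors(weights, flat)
      }
      lossHist[ep] <- epLoss / nT
    }
    new("UNetSegmenter", weights = weights, config = config,
        lossHistory = lossHist)
  })
}

#' Predict a foreground probability map
#'
#' @param model a [UNetSegmenter-class] (trained or freshly initialized via
#'   [trainSegmenter()] with 0 epochs).
#' @param tile H x W x 3 tile (8-bit array or [renderTile()] result); sides
#'   must be multiples of `2^(depth-1)`.
#' @return Numeric matrix of per-pixel foreground probabilities in [0, 1],
#'   same spatial shape as the tile.
#' @export
predictSegmenter <- function(model, tile) {
  if (!is(model, "UNetSegmenter")) validationError("model must be a UNetSegmenter")
  tile <- asTileArray(tile)
  assertTile(tile)
  div <- 2^(model@config$depth - 1L)
  if (any(dim(tile)[1:2] %% div != 0)) {
    validationError(sprintf(
      "tile sides must be multiples of %d for depth %d",
      div, model@config$depth))
  }
  unetForward(model@weights, tile / 255)$prob
}

#' Save / reload a segmenter checkpoint
#'
#' @param model a [UNetSegmenter-class].
#' @param path checkpoint file path.
#' @return `loadSegmenter()` returns the restored [UNetSegmenter-class];
#'   `saveSegmenter()` returns `path` invisibly.
#' @export
saveSegmenter <- function(model, path) {
  saveRDS(list(weights = model@weights, config = model@config,
               lossHistory = model@lossHistory), path)
  invisible(path)
}

#' @rdname saveSegmenter
#' @export
loadSegmenter <- function(path) {
  if (!file.exists(path)) ioError(paste("no checkpoint at", path))
  x <- readRDS(path)
  new("UNetSegmenter", weights = x$weights, config = x$config,
      lossHistory = x$lossHistory)
}
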