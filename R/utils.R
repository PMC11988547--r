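## Internal helpers shared across modules.

#' @importFrom methods new validObject is slot
#' @importFrom stats rnorm runif rexp rnbinom rbinom var cor.test sd
#'   quantile predict aggregate
#' @importFrom utils head write.table read.delim
NULL

## Structured conditions -----------------------------------------------------

stopNucleo <- function(msg, class, call = sys.call(-1)) {
  stop(structure(
    class = c(class, "nucleomicsError", "error", "condition"),
    list(message = msg, call = call)
  ))
}

configError <- function(msg) stopNucleo(msg, "nucleomicsConfigError")
validationError <- function(msg) stopNucleo(msg, "nucleomicsValidationError")
degenerateError <- function(msg) stopNucleo(msg, "nucleomicsDegenerateError")
ioError <- function(msg) stopNucleo(msg, "nucleomicsIOError")

## RNG ------------------------------------------------------------------------

# Evaluate `expr` under a local RNG stream seeded with `seed`, restoring the
# caller's RNG state afterwards so library code never perturbs user sessions.
withSeed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      get(".Random.seed", globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  expr
}

# Derive a child seed from a base seed and a stream index, kept within the
# 32-bit signed integer range.
childSeed <- function(seed, index) {
  as.integer((as.double(seed) * 7919 + 104729 * as.double(index)) %% 2147483647)
}

## Tiles ----------------------------------------------------------------------

# Tiles are plain integer arrays H x W x 3 with 8-bit channel values.
assertTile <- function(x, what = "tile") {
  if (!is.array(x) || length(dim(x)) != 3L || dim(x)[3] != 3L) {
    validationError(sprintf("%s must be an H x W x 3 array", what))
  }
  if (min(x) < 0 || max(x) > 255) {
    validationError(sprintf("%s channel values must lie in [0, 255]", what))
  }
  invisible(TRUE)
}

# Rec. 601 luma; tiles are 8-bit so the result stays on the 0..255 scale.
tileToGray <- function(tile) {
  0.299 * tile[, , 1] + 0.587 * tile[, , 2] + 0.114 * tile[, , 3]
}

clamp255 <- function(x) pmin(pmax(round(x), 0), 255)

# Accept a bare pixel array, a tileImage() element ($pixels) or a
# renderTile() result ($tile).
asTileArray <- function(x) {
  if (is.list(x)) x <- x$pixels %||% x$tile
  x
}

popVar <- function(x) {
  m <- mean(x)
  mean((x - m)^2)
}
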