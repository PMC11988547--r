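# Instance labeling, Otsu thresholding and the area/compactness filter.

test_that("labeling uses 8-connectivity and row-major numbering", {
  m <- matrix(0L, 6, 6)
  m[2, 2] <- 1L; m[3, 3] <- 1L       # diagonal touch: one component
  expect_equal(max(labelConnected(m)), 1L)

  m2 <- matrix(0L, 8, 8)
  m2[2:3, 2:3] <- 1L; m2[6:7, 5:6] <- 1L
  lab <- labelConnected(m2)
  expect_equal(max(lab), 2L)
  expect_equal(lab[2, 2], 1L)        # first in row-major order
  expect_equal(lab[6, 5], 2L)
})

test_that("binarize_and_label measures components with the boundary-walk perimeter", {
  expect_equal(nrow(measures(binarizeAndLabel(matrix(0, 10, 10)))), 0L)

  m <- matrix(0, 20, 20)
  m[3:7, 3:7] <- 1                   # 5x5 square
  m[12:17, 10:16] <- 1
  ns <- binarizeAndLabel(m)
  meas <- measures(ns)
  expect_equal(nrow(meas), 2L)
  expect_equal(meas$area[1], 25)
  # 5x5 square: 16 boundary pixels, all unit steps -> P = 16
  expect_equal(meas$perimeter[1], 16)
  expect_equal(meas$compactness[1], 16^2 / 25)

  # probability maps outside [0,1] are rejected
  expect_error(binarizeAndLabel(matrix(2, 4, 4)),
               class = "nucleomicsValidationError")
})

test_that("otsuThreshold equals exhaustive between-class-variance search", {
  thr <- otsuThreshold(c(1, 1, 1, 9, 9, 9), nBins = 8L)
  expect_gt(thr, 1); expect_lt(thr, 9)

  expect_error(otsuThreshold(c(5, 5, 5)), class = "nucleomicsDegenerateError")

  set.seed(7)
  for (k in 1:5) {
    vals <- c(rnorm(120, 4, 1), rnorm(80, 14, 2))
    expect_identical(otsuThreshold(vals, 64L), otsuBrute(vals, 64L))
  }
  # and on a non-bimodal sample the two implementations still agree
  vals <- rexp(200, 0.2)
  expect_identical(otsuThreshold(vals, 64L), otsuBrute(vals, 64L))
})

test_that("the filter removes small-area and high-compactness instances", {
  mkSet <- function(area, comp) {
    new("NucleusSet", tileId = "t", labels = matrix(0L, 1, 1),
        measures = data.frame(label = seq_along(area), area = area,
                              perimeter = sqrt(comp * area),
                              compactness = comp),
        kept = rep(NA, length(area)),
        areaThreshold = NA_real_, compactnessThreshold = NA_real_)
  }

  # areas {4, 5, 100, 110}, equal compactness: area criterion only
  ns <- mkSet(c(4, 5, 100, 110), rep(13, 4))
  suppressMessages(f <- filterInstances(ns))
  expect_equal(f@areaThreshold, otsuBrute(c(4, 5, 100, 110), 64L))
  expect_true(is.na(f@compactnessThreshold))
  expect_equal(f@kept, c(FALSE, FALSE, TRUE, TRUE))

  # all identical: both criteria degenerate, everything kept
  ns2 <- mkSet(rep(50, 4), rep(13, 4))
  suppressMessages(f2 <- filterInstances(ns2))
  expect_true(all(f2@kept))

  # a perfect disc (C = 4 pi) among jagged instances (C > 30) is kept
  ns3 <- mkSet(rep(80, 5), c(4 * pi, 33, 35, 38, 31))
  suppressMessages(f3 <- filterInstances(ns3))
  expect_true(f3@kept[1])
  expect_false(any(f3@kept[2:5]))

  # partition invariant: kept + removed = input
  expect_equal(sum(f3@kept) + sum(!f3@kept), 5L)
})

test_that("shrinking an instance below the area threshold removes it", {
  mkSet <- function(area) new(
    "NucleusSet", tileId = "t", labels = matrix(0L, 1, 1),
    measures = data.frame(label = seq_along(area), area = area,
                          perimeter = 20, compactness = 400 / area),
    kept = rep(NA, length(area)), areaThreshold = NA_real_,
    compactnessThreshold = NA_real_)
  areas <- c(30, 40, 200, 210, 220)
  suppressMessages(f <- filterInstances(mkSet(areas)))
  expect_true(f@kept[3])
  # shrink instance 3 into the small-area mode, others fixed
  areas2 <- areas; areas2[3] <- 35
  suppressMessages(f2 <- filterInstances(mkSet(areas2)))
  expect_false(f2@kept[3])
  expect_equal(f2@kept[-3], f@kept[-3])
})

test_that("LabelMe polygons rasterize with the even-odd rule", {
  # an axis-aligned square with vertices at pixel centers
  poly <- cbind(c(3, 8, 8, 3), c(2, 2, 6, 6))
  mask <- rasterizePolygons(list(poly), 10, 12)
  expect_equal(sum(mask), 0L + sum(mask[2:6, 3:8]))
  expect_equal(dim(mask), c(10L, 12L))

  # round-trip through a LabelMe file
  path <- withr::local_tempfile(fileext = ".json")
  writeLabelMe(list(poly), path, "img.png", 10L, 12L)
  back <- readLabelMe(path)
  expect_equal(back$height, 10L)
  expect_identical(rasterizePolygons(back), mask)
})
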