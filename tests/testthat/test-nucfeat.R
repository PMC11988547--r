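# The 20 nuclear features: color statistics, shape descriptors, Hu
# invariants, wavelet texture, and the feature-table contract.

test_that("color statistics are the population mean/variance over the nucleus", {
  tile <- flatTile(10, 10, c(120, 30, 200))
  mask <- matrix(0, 10, 10); mask[3:6, 3:6] <- 1
  cs <- colorStats(tile, mask)
  expect_equal(unname(cs[c("R_average", "G_average", "B_average")]),
               c(120, 30, 200))
  expect_equal(unname(cs[c("R_var", "G_var", "B_var")]), c(0, 0, 0))

  # two pixels valued 0 and 2: mean 1, population variance 1
  t2 <- flatTile(2, 2, c(0, 0, 0)); t2[1, 2, 1] <- 2L
  m2 <- matrix(c(1, 0, 1, 0), 2, 2)
  expect_equal(unname(colorStats(t2, m2)[c("R_average", "R_var")]), c(1, 1))

  # random 50-pixel instance equals a direct loop-summation oracle
  set.seed(3)
  t3 <- array(sample(0:255, 300, TRUE), c(10, 10, 3))
  m3 <- matrix(0, 10, 10); m3[sample(100, 50)] <- 1
  cs3 <- colorStats(t3, m3)
  for (ch in 1:3) {
    vals <- numeric(0)
    for (r in 1:10) for (cc in 1:10) {
      if (m3[r, cc] > 0) vals <- c(vals, t3[r, cc, ch])
    }
    expect_equal(unname(cs3[ch]), sum(vals) / length(vals))
    expect_equal(unname(cs3[ch + 3]),
                 sum((vals - mean(vals))^2) / length(vals))
  }
  expect_error(colorStats(tile, matrix(0, 10, 10)),
               class = "nucleomicsValidationError")
})

test_that("shape descriptors satisfy the analytic identities", {
  # moment-ellipse eccentricity: a = 5, b = 3 -> E = 0.8 (raster tolerance)
  m <- ellipseMask(40, 40, 20, 20, 15, 9)
  sd1 <- shapeDescriptors(m)
  expect_lt(abs(sd1$Eccentric - 0.8), 0.02)

  # compactness x circularity = 4 pi identically
  expect_equal(sd1$Compactness * sd1$Circularity, 4 * pi)

  # a large rasterized disc approaches the continuous limits
  disc <- ellipseMask(100, 100, 50, 50, 40, 40)
  sdd <- shapeDescriptors(disc)
  expect_equal(sdd$Eccentric, 0, tolerance = 0.05)
  # boundary-walk perimeter overestimates a smooth circle by ~5%,
  # so rasterized circularity sits just below 1 (see vignette)
  expect_gt(sdd$Circularity, 0.85)
  expect_lt(sdd$Circularity, 1.02)
  expect_gt(sdd$Compactness, 4 * pi - 0.5)

  # degenerate 1-px line is flagged, minor axis clamped
  line <- matrix(0, 5, 9); line[3, 2:8] <- 1
  sdl <- shapeDescriptors(line)
  expect_true(attr(sdl, "degenerate"))
  expect_lt(sdl$Eccentric, 1)
})

test_that("holes are filled before measurement", {
  ring <- ellipseMask(40, 40, 20, 20, 12, 12)
  hole <- ellipseMask(40, 40, 20, 20, 5, 5)
  ring[hole == 1] <- 0
  filled <- shapeDescriptors(ring)
  expect_equal(filled$A, sum(ellipseMask(40, 40, 20, 20, 12, 12)))
})

test_that("Hu invariants match the naive summation oracle exactly", {
  set.seed(11)
  for (k in 1:6) {
    m <- matrix(rbinom(9 * 7, 1, 0.5), 9, 7)
    if (!any(m > 0)) m[5, 4] <- 1
    expect_identical(unname(huMoments(m)), huBrute(m))
  }
  # larger random blobs up to 32 x 32, still exact
  for (k in 1:3) {
    m <- matrix(rbinom(32 * 32, 1, 0.3), 32, 32)
    expect_identical(unname(huMoments(m)), huBrute(m))
  }
})

test_that("moment normalization satisfies its defining identities", {
  m <- ellipseMask(30, 30, 15, 15, 10, 6, 0.7)
  mo <- momentSet(m)
  expect_equal(mo$mu[1, 1], mo$m[1, 1])
  expect_equal(mo$mu[2, 1], 0, tolerance = 1e-9)
  expect_equal(mo$mu[1, 2], 0, tolerance = 1e-9)
  expect_equal(mo$eta[1, 1], 1)
})

test_that("Hu invariances: translation exact, rotation and scale within tolerance", {
  blob <- matrix(0, 40, 40)
  blob[8:20, 10:25] <- 1; blob[15:30, 18:22] <- 1
  hu <- huMoments(blob)

  # translation by (+17, -6): bit-identical
  big <- matrix(0, 80, 80)
  big[8:20 + 17, 10:25 + 30] <- 1; big[15:30 + 17, 18:22 + 30] <- 1
  expect_identical(huMoments(big), hu)

  # lattice-exact 90 degree rotation: equal to machine precision
  rot <- t(blob)[ncol(blob):1, ]
  expect_equal(huMoments(rot), hu, tolerance = 1e-12)

  # uniform 2x scaling of a >= 400 px shape: within 1% relative
  m1 <- ellipseMask(60, 60, 30, 30, 18, 11, 0.5)
  m2 <- ellipseMask(120, 120, 60, 60, 36, 22, 0.5)
  h1 <- huMoments(m1); h2 <- huMoments(m2)
  expect_lt(max(abs(h2[1:2] - h1[1:2]) / abs(h1[1:2])), 0.01)
})

test_that("the one-level DWT matches direct filter-bank evaluation", {
  # constant patch: high-pass of a constant is zero
  wt <- waveletTexture(flatTile(8, 8, c(100, 100, 100)),
                       matrix(1, 8, 8))
  expect_equal(unname(wt), c(0, 0))

  # 2x2 patch [[1,0],[0,1]] with Haar: cD = 1 by hand evaluation
  expect_equal(as.vector(dwt2(matrix(c(1, 0, 0, 1), 2, 2, byrow = TRUE))$cD), 1)

  # 16x16 random patch: all four subbands match the separable oracle
  set.seed(4)
  x <- matrix(rnorm(256), 16, 16)
  expect_equal(dwt2(x)$cD, dwt2Brute(x), tolerance = 1e-12)

  expect_error(dwt2(matrix(1, 1, 1)), class = "nucleomicsValidationError")
})

test_that("the feature table keeps its 20-column contract", {
  co <- smallCohort(seed = 5)
  rt <- renderTile(co, 1, 12, seed = 6, tileSize = 160)
  ns <- binarizeAndLabel(rt$mask, tileId = "t0")
  ft <- extractFeatures(rt$tile, ns, patientId = "P1")
  expect_equal(nrow(ft), 12L)
  expect_identical(setdiff(names(ft), c("patient_id", "tile_id", "label")),
                   nuclearFeatureNames())

  empty <- extractFeatures(rt$tile,
                           binarizeAndLabel(matrix(0, 64, 64), tileId = "e"))
  expect_equal(nrow(empty), 0L)
  expect_identical(setdiff(names(empty), c("patient_id", "tile_id", "label")),
                   nuclearFeatureNames())

  # per-tile wavelet scope yields one shared cD statistic pair
  ft2 <- extractFeatures(rt$tile, ns, scope = "tile")
  expect_length(unique(ft2$cD_var), 1L)
})

test_that("eccentricity separates discs from 3:1 ellipses", {
  discs <- lapply(1:6, function(i) ellipseMask(40, 40, 20, 20, 15, 15))
  ells <- lapply(1:6, function(i) ellipseMask(70, 70, 35, 35, 30, 10))
  eD <- vapply(discs, function(m) shapeDescriptors(m)$Eccentric, numeric(1))
  eE <- vapply(ells, function(m) shapeDescriptors(m)$Eccentric, numeric(1))
  # analytic values 0 vs sqrt(1 - 1/9) = 0.943
  expect_gt(mean(eE) - mean(eD), 0.5)
  expect_lt(abs(mean(eE) - sqrt(1 - 1 / 9)), 0.05)
})
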