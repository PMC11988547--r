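# Synthetic cohort generator: determinism, forced counts, null behavior,
# rendering ground truth.

test_that("cohort counts and determinism follow the cohort specification and seed", {
  spec <- cohortSpec(nPatientsClass1 = 3, nPatientsClass2 = 2, seed = 7)
  co <- generateCohort(spec)
  expect_equal(nrow(patients(co)), 5L)
  expect_equal(sum(patients(co)$subtype == 1L), 3L)

  co2 <- generateCohort(cohortSpec(nPatientsClass1 = 3, nPatientsClass2 = 2,
                                   seed = 7))
  expect_identical(patients(co), patients(co2))
  expect_identical(co@cnv, co2@cnv)
  expect_identical(co@snv, co2@snv)
  expect_identical(co@expression, co2@expression)

  rt1 <- renderTile(co, 1, 5, seed = 3, tileSize = 96)
  rt2 <- renderTile(co2, 1, 5, seed = 3, tileSize = 96)
  expect_identical(rt1$tile, rt2$tile)
  expect_identical(rt1$mask, rt2$mask)
})

test_that("invalid cohort specifications are rejected as configuration errors", {
  expect_error(cohortSpec(nPatientsClass1 = 0), class = "nucleomicsConfigError")
  expect_error(cohortSpec(tileSize = 32), class = "nucleomicsConfigError")
  expect_error(cohortSpec(censoringRate = 1.5), class = "nucleomicsConfigError")
})

test_that("zero class effect yields a null generator", {
  # Monte-Carlo check: with no planted effect, a two-sample t-test on the
  # patient-mean nuclear area is non-significant at alpha = 0.01 in at
  # least 95% of replicate cohorts.
  nullEffect <- c(area = 0, eccentricity = 0, color = 0, expression = 0)
  reps <- 100L
  hits <- 0L
  for (k in seq_len(reps)) {
    co <- generateCohort(cohortSpec(nPatientsClass1 = 200,
                                    nPatientsClass2 = 200,
                                    classEffect = nullEffect, seed = 1000 + k))
    ft <- simulateFeatureCohort(co, seed = 2000 + k, nucleiPerPatient = 1L)
    cls <- patients(co)$subtype[match(ft$patient_id, patients(co)$patientId)]
    p <- t.test(ft$Area[cls == 1], ft$Area[cls == 2])$p.value
    if (p >= 0.01) hits <- hits + 1L
  }
  expect_gte(hits, 95L)
})

test_that("increasing the planted area effect widens the class separation", {
  gaps <- vapply(c(0.3, 0.8, 1.5), function(eff) {
    co <- generateCohort(cohortSpec(
      nPatientsClass1 = 80, nPatientsClass2 = 80,
      classEffect = c(area = eff, eccentricity = 0, color = 0, expression = 0),
      seed = 31))
    ft <- simulateFeatureCohort(co, seed = 32, nucleiPerPatient = 20L)
    cls <- patients(co)$subtype[match(ft$patient_id, patients(co)$patientId)]
    mean(ft$Area[cls == 2]) - mean(ft$Area[cls == 1])
  }, numeric(1))
  expect_true(all(diff(gaps) > 0))
})

test_that("rendered tiles carry exact ground truth", {
  co <- smallCohort(seed = 5)
  blank <- renderTile(co, 1, 0, seed = 1, tileSize = 96)
  expect_equal(sum(blank$mask), 0)
  expect_equal(nrow(blank$instances), 0L)

  rt <- renderTile(co, 2, 10, seed = 11, tileSize = 192)
  expect_equal(rt$placed, 10L)
  # overlap is disallowed: one 8-connected component per placed nucleus
  expect_equal(max(labelConnected(rt$mask)), rt$placed)
  expect_equal(nrow(rt$instances), rt$placed)
  # the mask is the exact union of the rendered ellipses
  union <- matrix(0L, 192, 192)
  for (k in seq_len(nrow(rt$instances))) {
    union <- pmax(union, ellipseMask(192, 192, rt$instances$cx[k],
                                     rt$instances$cy[k], rt$instances$a[k],
                                     rt$instances$b[k], rt$instances$angle[k]))
  }
  expect_identical(rt$mask, union)
})

test_that("overflowing placement is reported, never silent", {
  co <- smallCohort(seed = 5)
  expect_warning(rt <- renderTile(co, 1, 60, seed = 2, tileSize = 64),
                 "placed")
  expect_lt(rt$placed, 60L)
  expect_equal(nrow(rt$instances), rt$placed)
})

test_that("a rendered ellipse's eccentricity is recovered from its own mask", {
  # axes a = 20, b = 10 -> E = sqrt(400 - 100)/20 = 0.866
  m <- ellipseMask(64, 64, 32, 32, 20, 10, theta = 0.4)
  sd1 <- shapeDescriptors(m)
  expect_lt(abs(sd1$Eccentric - sqrt(300) / 20), 0.05)
})

test_that("survival generation respects the censoring model", {
  co <- generateCohort(cohortSpec(nPatientsClass1 = 400, nPatientsClass2 = 400,
                                  censoringRate = 0.4, seed = 9))
  pat <- patients(co)
  expect_true(all(pat$osTime >= 0))
  expect_lt(abs(mean(pat$css == "alive") - 0.4), 0.06)
  # class 2 has the higher hazard: shorter event times on average
  dead <- pat[pat$css == "dead", ]
  expect_gt(mean(dead$osTime[dead$subtype == 1]),
            mean(dead$osTime[dead$subtype == 2]))
})

test_that("a cohort round-trips through its on-disk form", {
  co <- smallCohort(n1 = 3, n2 = 2, seed = 17)
  dir <- withr::local_tempdir()
  man <- writeCohort(co, dir, renderPatients = 1L, nucleiPerTile = 5L,
                     tileSize = 96)
  expect_true(all(file.exists(man$file)))
  expect_setequal(unique(man$kind),
                  c("clinical", "cnv", "snv", "mrna", "tile", "mask",
                    "annotation"))

  clin <- readClinicalTable(file.path(dir, "clinical.tsv"))
  expect_equal(nrow(clin), 5L)
  genes <- co@spec@genes
  cnv <- readCnvTable(file.path(dir, "cnv.tsv"), genes)
  expect_equal(dim(cnv), c(length(genes), 5L))
  expect_equal(unname(cnv["TP53", clin$patient_id[1]]),
               round(co@cnv["TP53", clin$patient_id[1]], 4))
  expr <- readExpressionTable(file.path(dir, "mrna.tsv"), genes)
  expect_equal(dim(expr), c(length(genes), 5L))
  snv <- readSnvTable(file.path(dir, "snv.tsv"), genes)
  expect_true(all(snv %in% c(0L, 1L)))

  # annotation polygons rasterize back close to the rendered mask
  tileFiles <- man[man$kind == "annotation", "file"]
  ann <- readLabelMe(tileFiles[1])
  mask <- png::readPNG(man[man$kind == "mask", "file"][1])
  rast <- rasterizePolygons(ann$polygons, nrow(mask), ncol(mask))
  expect_gt(diceCoefficient(rast, mask > 0), 0.85)
})
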