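# Factor encoding, survival labels, balancing, splitting and assembly.

test_that("clinical encodings follow the fixed vocabulary", {
  raw <- data.frame(sex = c("Male", "Female"), race = c("White", NA),
                    age_at_diagnosis = c(66, 59),
                    T = c("T2", "TX"), N = c("N0", "NX"),
                    M = c("M0", "MX"), stage = c("Stage I", "Stage IV"))
  enc <- encodeClinical(raw)
  expect_equal(enc$Gender, c(1L, 2L))
  expect_equal(enc$Race, c(4L, 0L))          # absent race -> Unreported
  expect_equal(enc$T, c(2L, 5L))
  expect_equal(enc$N, c(1L, 5L))
  expect_equal(enc$M, c(1L, 5L))
  expect_equal(enc$Stage, c(1L, 4L))

  # unmapped values in any non-race field raise a validation error
  expect_error(encodeClinical(data.frame(T = "T9")),
               class = "nucleomicsValidationError")
  expect_error(encodeClinical(data.frame(sex = "unknown")),
               class = "nucleomicsValidationError")
})

test_that("encoding round-trips over every vocabulary", {
  for (field in c("sex", "race", "T", "N", "M", "stage")) {
    vocab <- names(NucleoMics:::.clinicalMaps[[field]])
    raw <- data.frame(v = vocab)
    names(raw) <- if (field %in% c("T", "N", "M")) field else field
    enc <- encodeClinical(raw)
    col <- c(sex = "Gender", race = "Race", T = "T", N = "N", M = "M",
             stage = "Stage")[[field]]
    expect_identical(decodeClinical(field, enc[[col]]), vocab)
  }
})

test_that("survival labels implement the three-class rule", {
  expect_equal(survivalLabel("dead", 180, 365), 1L)
  expect_equal(survivalLabel("alive", 800, 365), 2L)
  expect_equal(survivalLabel("alive", 100, 365), 0L)   # the only unknown case
  expect_equal(survivalLabel("dead", 800, 365), 2L)    # survived the horizon
  expect_equal(survivalLabel("dead", 365, 365), 2L)    # boundary: >= horizon
  expect_error(survivalLabel("dead", -1, 365),
               class = "nucleomicsValidationError")
})

test_that("CNV amplitude classes use open intervals with lower-class ties", {
  expect_equal(cnvCode(c(0.05, 0.5, 1.2)), c(0L, 1L, 2L))
  expect_equal(cnvCode(c(0.1, 0.9)), c(0L, 1L))        # boundary tie rule
  expect_error(cnvCode(-0.2), class = "nucleomicsValidationError")
})

test_that("SNV classes form a closed vocabulary", {
  expect_equal(snvCode("Missense"), 1L)
  expect_equal(snvCode("Silent"), 0L)
  expect_equal(snvCode(c("Splice_Site", "Intron", "3'UTR")), c(1L, 0L, 0L))
  expect_error(snvCode("Nonsense_Mutation"),
               class = "nucleomicsValidationError")
})

test_that("balancing yields exactly the target with the right sampling rule", {
  rows <- data.frame(id = 1:350, v = rnorm(350))
  under <- balancePatient(rows, 200L, seed = 3)
  expect_equal(nrow(under), 200L)
  expect_equal(anyDuplicated(under$id), 0L)            # without replacement

  rows2 <- data.frame(id = 1:50, v = rnorm(50))
  over <- balancePatient(rows2, 200L, seed = 4)
  expect_equal(nrow(over), 200L)
  expect_setequal(unique(over$id), 1:50)               # all originals present

  same <- data.frame(id = 1:200)
  expect_identical(balancePatient(same, 200L, seed = 5), same)

  expect_warning(out <- balancePatient(same[0, , drop = FALSE], 200L),
                 "zero")
  expect_equal(nrow(out), 0L)

  # determinism
  expect_identical(balancePatient(rows, 200L, seed = 3), under)
})

test_that("patient-level splitting reproduces the printed cohort arithmetic", {
  ids <- sprintf("P%04d", 1:1252)
  subtype <- rep(c(1L, 2L), c(525L, 727L))
  part <- splitPatients(ids, subtype, seed = 1)
  expect_equal(as.integer(table(part)[c("train", "validation", "test")]),
               c(752L, 250L, 250L))
  # per-stratum training counts: exact 60% of 525, remainder rule for 727
  expect_equal(sum(part == "train" & subtype == 1L), 315L)
  expect_equal(sum(part == "train" & subtype == 2L), 437L)
  expect_equal(sum(part == "validation" & subtype == 1L), 105L)
  # no patient in two partitions, all assigned
  expect_equal(sort(names(part)), sort(ids))

  small <- splitPatients(sprintf("Q%02d", 1:10), rep(1L, 10), seed = 2)
  expect_equal(as.integer(table(small)[c("train", "validation", "test")]),
               c(6L, 2L, 2L))

  expect_error(splitPatients(c("a", "b"), c(1, 1), seed = 1),
               class = "nucleomicsValidationError")
  expect_error(splitPatients(ids, fractions = c(0.5, 0.2, 0.2)),
               class = "nucleomicsValidationError")
})

test_that("assembly produces the documented design matrices", {
  co <- smallCohort(n1 = 3, n2 = 3, seed = 23)
  ft <- simulateFeatureCohort(co, seed = 24, nucleiPerPatient = 30L)

  ads <- assembleDataset(ft, co, task = "subtype", target = 200L, seed = 25)
  expect_equal(length(ads@featureColumns), 46L)        # 20 nuclear + 26 mRNA
  expect_equal(nrow(ads@data), 6L * 200L)
  expect_s4_class(ads, "AssembledDataset")

  os <- assembleDataset(ft, co, task = "os2", target = 200L, seed = 25)
  expect_equal(length(os@featureColumns), 95L)         # 20+7+15+27+26
  expect_true(all(taskLabels(os) %in% 0:2))

  # partition is disjoint and exhaustive over patients
  part <- partition(ads)
  expect_setequal(names(part), patients(co)$patientId)
  expect_true(all(part %in% c("train", "validation", "test")))

  # 3 patients x 200 rows per partition relation
  trainRows <- nrow(designMatrix(ads, "train"))
  expect_equal(trainRows %% 200L, 0L)

  # patients with features but no factor record are dropped with a message
  ft2 <- rbind(ft, transform(ft[1:3, ], patient_id = "GHOST"))
  expect_message(assembleDataset(ft2, co, task = "subtype", target = 50L,
                                 seed = 26), "dropped")

  # the unknown survival class can be excluded on request
  os0 <- assembleDataset(ft, co, task = "os1", target = 100L,
                         dropUnknown = TRUE, seed = 27)
  expect_false(any(taskLabels(os0) == 0L))
})
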