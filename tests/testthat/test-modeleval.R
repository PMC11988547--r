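# Metrics, ROC/AUC, tuning and the experiment driver.

test_that("metrics from confusion counts follow the four formulas", {
  m <- metricsFromCounts(tp = 50, fp = 5, tn = 40, fn = 5)
  expect_equal(m$accuracy, 0.90)
  expect_equal(m$precision, 50 / 55)
  expect_equal(m$recall, 50 / 55)
  expect_equal(m$f1, 50 / 55)

  perfect <- classificationMetrics(c(1, 1, 2, 2), c(1, 1, 2, 2))
  expect_equal(perfect$accuracy, 1)
  expect_equal(perfect$precision, 1)
  expect_equal(perfect$recall, 1)
  expect_equal(perfect$f1, 1)
})

test_that("multiclass metrics equal hand-computed one-vs-rest values", {
  # fixed 3x3 confusion: rows = truth 0,1,2
  yTrue <- rep(c(0, 1, 2), c(10, 8, 6))
  yPred <- c(rep(0, 7), rep(1, 2), 2,      # truth 0
             rep(1, 5), rep(0, 2), 2,      # truth 1
             rep(2, 4), 0, 1)              # truth 2
  m <- classificationMetrics(yTrue, yPred)
  expect_equal(m$accuracy, (7 + 5 + 4) / 24)
  # per-class one-vs-rest by enumeration
  prec <- c(7 / (7 + 2 + 1), 5 / (5 + 2 + 1), 4 / (4 + 1 + 1))
  rec <- c(7 / 10, 5 / 8, 4 / 6)
  f1 <- 2 * prec * rec / (prec + rec)
  expect_equal(m$precision, mean(prec))
  expect_equal(m$recall, mean(rec))
  expect_equal(m$f1, mean(f1))
  expect_equal(sum(m$confusion), 24)
  expect_equal(unname(rowSums(m$confusion)), c(10, 8, 6))

  # F1 = precision = recall whenever precision = recall
  expect_equal(metricsFromCounts(30, 10, 50, 10)$f1,
               metricsFromCounts(30, 10, 50, 10)$precision)

  # a class absent from the truth is excluded from the macro mean
  expect_message(m2 <- classificationMetrics(c(1, 1, 2), c(1, 3, 2),
                                             classes = c(1, 2, 3)),
                 "absent")
  expect_false(is.nan(m2$f1))
})

test_that("trapezoidal AUC equals the rank statistic", {
  expect_equal(rocAuc(c(0, 0, 1, 1), c(0.1, 0.2, 0.8, 0.9))$auc, 1)
  expect_equal(rocAuc(c(0, 1, 0, 1), rep(0.5, 4))$auc, 0.5)

  set.seed(31)
  for (k in 1:5) {
    y <- rbinom(20, 1, 0.5)
    if (length(unique(y)) < 2) y[1:2] <- 0:1
    s <- round(rnorm(20), 1)           # ties included
    expect_equal(rocAuc(y, s)$auc, aucMannWhitney(y, s), tolerance = 1e-12)
  }
  expect_error(rocAuc(rep(1, 5), rnorm(5)),
               class = "nucleomicsDegenerateError")

  # multiclass: macro mean of one-vs-rest AUCs
  y3 <- rep(c(1, 2, 3), each = 10)
  set.seed(32)
  sc <- matrix(runif(90), 30, 3, dimnames = list(NULL, c("1", "2", "3")))
  got <- rocAuc(y3, sc)
  per <- vapply(c("1", "2", "3"), function(cl) {
    aucMannWhitney(as.integer(y3 == as.integer(cl)), sc[, cl])
  }, numeric(1))
  expect_equal(got$auc, mean(per), tolerance = 1e-12)
})

test_that("every family fits and predicts coherent probabilities", {
  set.seed(33)
  n <- 240
  x <- matrix(rnorm(n * 5), n, 5, dimnames = list(NULL, paste0("f", 1:5)))
  y <- ifelse(x[, 1] + 0.8 * x[, 2] + rnorm(n, 0, 0.7) > 0, 2L, 1L)
  xT <- matrix(rnorm(60 * 5), 60, 5, dimnames = list(NULL, paste0("f", 1:5)))
  yT <- ifelse(xT[, 1] + 0.8 * xT[, 2] > 0, 2L, 1L)
  for (fam in c("xgboost", "randomForest", "adaboost", "mlp")) {
    cfg <- switch(fam, xgboost = list(nrounds = 40L),
                  adaboost = list(n_estimators = 40L), list())
    fit <- fitModel(fam, x, y, cfg, seed = 7)
    p <- predictModel(fit, xT)
    expect_equal(dim(p), c(60L, 2L))
    expect_equal(unname(rowSums(p)), rep(1, 60), tolerance = 1e-6)
    expect_gt(rocAuc(yT, p)$auc, 0.8)
  }
  # both AdaBoost dialects learn the signal
  fitS <- fitModel("adaboost", x, y,
                   list(n_estimators = 40L, algorithm = "SAMME"), seed = 7)
  expect_gt(rocAuc(yT, predictModel(fitS, xT))$auc, 0.8)
})

test_that("tuning returns the validation-accuracy argmax with a full log", {
  set.seed(34)
  n <- 200
  x <- matrix(rnorm(n * 4), n, 4, dimnames = list(NULL, paste0("f", 1:4)))
  y <- ifelse(x[, 1] > 0, 2L, 1L)
  xv <- matrix(rnorm(80 * 4), 80, 4, dimnames = list(NULL, paste0("f", 1:4)))
  yv <- ifelse(xv[, 1] > 0, 2L, 1L)

  single <- list(family = "xgboost",
                 grid = list(eta = 0.3, max_depth = 3L, nrounds = 20L))
  t1 <- tuneModel(single, x, y, xv, yv, budget = 5L, seed = 1)
  expect_equal(t1$best, list(eta = 0.3, max_depth = 3L, nrounds = 20L))
  expect_equal(nrow(t1$trials), 1L)

  # a deep tree beats a stump on this separable task, so argmax picks it
  two <- list(family = "adaboost",
              grid = list(n_estimators = c(1L, 60L), learning_rate = 0.1))
  t2 <- tuneModel(two, x, y, xv, yv, budget = 10L, seed = 1)
  expect_equal(t2$best$n_estimators,
               t2$trials$n_estimators[which.max(t2$trials$validation_accuracy)])
  expect_gte(t2$bestAccuracy, max(t2$trials$validation_accuracy))
})

test_that("the experiment driver is deterministic and leak-free", {
  co <- smallCohort(n1 = 15, n2 = 15, seed = 51,
                    effect = c(area = 1.5, eccentricity = 0.8, color = 10,
                               expression = 1.0))
  ft <- simulateFeatureCohort(co, seed = 52, nucleiPerPatient = 25L)
  ads <- assembleDataset(ft, co, task = "subtype", target = 25L, seed = 53)

  spaces <- list(xgboost = list(family = "xgboost",
                                grid = list(eta = c(0.1, 0.3),
                                            max_depth = 3L, nrounds = 30L)))
  r1 <- runExperiment(ads, families = "xgboost", spaces = spaces,
                      budget = 2L, seed = 9)
  r2 <- runExperiment(ads, families = "xgboost", spaces = spaces,
                      budget = 2L, seed = 9)
  e1 <- evalResults(r1)$xgboost; e2 <- evalResults(r2)$xgboost
  expect_identical(e1$metrics, e2$metrics)
  expect_identical(e1$auc, e2$auc)
  expect_identical(e1$chosen, e2$chosen)

  # confusion matrix row sums equal the test class counts
  yTest <- taskLabels(ads, "test")
  expect_equal(unname(rowSums(e1$metrics$confusion)),
               unname(as.vector(table(yTest))))

  # patient-level partitions do not intersect
  part <- partition(ads)
  pid <- ads@data$patient_id
  expect_equal(length(intersect(pid[part[pid] == "train"],
                                pid[part[pid] == "test"])), 0L)

  # with permuted labels the test AUC concentrates near chance
  set.seed(54)
  adsPerm <- ads
  adsPerm@data$.label <- sample(adsPerm@data$.label)
  rp <- runExperiment(adsPerm, families = "xgboost", spaces = spaces,
                      budget = 2L, seed = 9)
  expect_lt(abs(evalResults(rp)$xgboost$auc - 0.5), 0.15)
})

test_that("an unknown family is reported as skipped, not dropped", {
  co <- smallCohort(n1 = 4, n2 = 4, seed = 61)
  ft <- simulateFeatureCohort(co, seed = 62, nucleiPerPatient = 10L)
  ads <- assembleDataset(ft, co, task = "subtype", target = 10L, seed = 63)
  rep <- runExperiment(ads, families = c("nosuchfamily"), budget = 1L, seed = 1)
  expect_null(evalResults(rep)$nosuchfamily$metrics)
  expect_match(evalResults(rep)$nosuchfamily$reason, "arg")
})
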