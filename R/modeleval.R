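## Hyperparameter search spaces, validation-accuracy tuning and the full
## train/validate/test experiment driver with metric reporting.

#' Default hyperparameter search space of a model family
#'
#' The candidate grids mirror the tabulated optimization ranges of the
#' study for the families available here: xgboost (eta, max_depth,
#' min_child_weight, gamma, subsample, colsample_bytree, lambda, alpha),
#' random forest (n_estimators, max_depth, min_samples_split,
#' min_samples_leaf), AdaBoost (n_estimators, algorithm, learning_rate)
#' and the feedforward network (hidden layer size, max_iter, weight-decay
#' alpha). Values not supported by the R backends (e.g. per-step learning
#' rates of stochastic solvers) are not exposed; see the vignette.
#'
#' @param family one of `modelFamilies()`.
#' @return List with elements `family` and `grid` (named list of candidate
#'   vectors).
#' @export
searchSpace <- function(family) {
  family <- match.arg(family, modelFamilies())
  grid <- switch(family,
    xgboost = list(
      eta = c(0.01, 0.05, 0.1, 0.3),
      max_depth = c(3L, 6L, 10L),
      min_child_weight = c(1, 3, 5, 10),
      gamma = c(0, 0.1, 0.5, 1),
      subsample = c(0.5, 0.7, 1),
      colsample_bytree = c(0.5, 0.7, 1),
      lambda = c(0, 0.1, 0.5, 1),
      alpha = c(0, 0.01, 0.1, 1)),
    randomForest = list(
      n_estimators = c(100L, 150L, 200L),
      max_depth = c(5L, 10L, 20L, 30L, 50L),
      min_samples_split = c(2L, 5L, 10L, 20L),
      min_samples_leaf = c(1L, 2L, 5L, 10L)),
    adaboost = list(
      n_estimators = c(50L, 75L, 100L, 125L, 150L, 175L, 200L),
      algorithm = c("SAMME.R", "SAMME"),
      learning_rate = c(0.01, 0.025, 0.05, 0.075, 0.1)),
    mlp = list(
      hidden_layer_sizes = c(50L, 100L),
      max_iter = c(100L, 200L, 300L),
      alpha = c(0.0001, 0.001, 0.01, 0.1)))
  list(family = family, grid = grid)
}

.gridSize <- function(grid) prod(vapply(grid, length, numeric(1)))

.sampleConfigs <- function(grid, budget, seed) {
  size <- .gridSize(grid)
  if (size <= budget) {
    configs <- do.call(expand.grid,
                       c(grid, stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE))
    return(lapply(seq_len(nrow(configs)), function(i) as.list(configs[i, ])))
  }
  withSeed(seed, {
    lapply(seq_len(budget), function(i) {
      lapply(grid, function(v) v[[sample.int(length(v), 1L)]])
    })
  })
}

#' Tune a family on the validation partition
#'
#' Enumerates the whole grid when it fits in `budget` trials, otherwise
#' draws `budget` seeded random configurations, fits each on the training
#' data and keeps the configuration maximizing validation accuracy (first
#' trial wins ties). The full trial log is returned for audit.
#'
#' @param space a [searchSpace()] (possibly with a reduced `grid`).
#' @param trainX,trainY training design matrix and labels.
#' @param valX,valY validation design matrix and labels.
#' @param budget maximum number of trials.
#' @param seed integer seed (config sampling and model fits).
#' @return List: `best` (config), `bestAccuracy`, `trials` (data.frame log).
#' @export
tuneModel <- function(space, trainX, trainY, valX, valY, budget = 12L,
                      seed = 1L) {
  if (!length(space$grid)) validationError("empty search space")
  configs <- .sampleConfigs(space$grid, budget, seed)
  acc <- numeric(length(configs))
  for (i in seq_along(configs)) {
    fit <- fitModel(space$family, trainX, trainY, configs[[i]],
                    seed = childSeed(seed, i))
    pred <- predictModel(fit, valX)
    yHat <- colnames(pred)[max.col(pred, ties.method = "first")]
    acc[i] <- mean(yHat == as.character(valY))
  }
  trials <- cbind(
    do.call(rbind, lapply(configs, function(cf) {
      as.data.frame(lapply(cf, function(v) v), stringsAsFactors = FALSE)
    })),
    validation_accuracy = acc)
  best <- which.max(acc)
  list(best = configs[[best]], bestAccuracy = acc[best], trials = trials)
}

#' Run the full modeling experiment
#'
#' For every requested family: tune hyperparameters on train/validation
#' ([tuneModel()]), refit the chosen configuration on the training
#' partition, and evaluate once on the held-out test partition --
#' accuracy, macro precision/recall/F1, confusion matrix, ROC and AUC
#' (macro one-vs-rest for the 3-class survival tasks), plus the wall-clock
#' fit duration (logged only; hardware-dependent). A family that fails is
#' reported as skipped with its error, never dropped silently.
#'
#' @param dataset an [AssembledDataset-class].
#' @param families character vector from `modelFamilies()`.
#' @param spaces optional named list of [searchSpace()] overrides.
#' @param factors optional character vector restricting the design matrix
#'   (e.g. the retained set of [screenFactors()]).
#' @param budget tuning trials per family.
#' @param seed integer seed.
#' @return An [EvalReport-class].
#' @export
runExperiment <- function(dataset, families = modelFamilies(), spaces = NULL,
                          factors = NULL, budget = 12L, seed = 1L) {
  if (!is(dataset, "AssembledDataset")) {
    validationError("dataset must be an AssembledDataset")
  }
  getXY <- function(part) {
    X <- designMatrix(dataset, subset = part)
    if (!is.null(factors)) X <- X[, factors, drop = FALSE]
    list(X = X, y = taskLabels(dataset, subset = part))
  }
  tr <- getXY("train"); va <- getXY("validation"); te <- getXY("test")

  results <- list()
  for (fam in families) {
    res <- tryCatch({
      space <- spaces[[fam]] %||% searchSpace(fam)
      tuned <- tuneModel(space, tr$X, tr$y, va$X, va$y, budget = budget,
                         seed = childSeed(seed, match(fam, families)))
      t0 <- Sys.time()
      fit <- fitModel(fam, tr$X, tr$y, tuned$best,
                      seed = childSeed(seed, 100L + match(fam, families)))
      duration <- as.numeric(Sys.time() - t0, units = "secs")
      prob <- predictModel(fit, te$X)
      yHat <- colnames(prob)[max.col(prob, ties.method = "first")]
      classes <- sort(unique(c(tr$y, te$y)))
      met <- classificationMetrics(as.character(te$y), yHat,
                                   classes = as.character(classes))
      roc <- rocAuc(te$y, prob)
      list(metrics = met, auc = roc$auc, roc = roc$roc %||% NULL,
           perClassAuc = roc$perClass %||% NULL,
           confusion = met$confusion, chosen = tuned$best,
           trials = tuned$trials, duration = duration)
    }, error = function(e) list(metrics = NULL, reason = conditionMessage(e)))
    results[[fam]] <- res
  }
  new("EvalReport", task = dataset@task, results = results)
}
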