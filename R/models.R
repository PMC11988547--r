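## Classifier family adapters behind one interface: fitModel() returns an
## object that predictModel() turns into a class-probability matrix.
## Gradient boosted trees via xgboost, random forest via randomForest,
## feedforward network via nnet, and an AdaBoost (SAMME / SAMME.R)
## implementation on rpart weak learners.

modelFamilies <- function() c("xgboost", "randomForest", "adaboost", "mlp")

#' Fit one classifier family
#'
#' @param family one of `modelFamilies()`: "xgboost" (gradient boosted
#'   trees), "randomForest", "adaboost" (SAMME / SAMME.R boosting of
#'   depth-limited rpart trees), "mlp" (single-hidden-layer feedforward
#'   network, BFGS-trained).
#' @param x numeric design matrix.
#' @param y label vector.
#' @param config named list of family hyperparameters (defaults filled
#'   from [searchSpace()] choices; see the vignette for the mapping).
#' @param seed integer seed; fits are deterministic given it.
#' @return An object for [predictModel()].
#' @export
fitModel <- function(family, x, y, config = list(), seed = 1L) {
  family <- match.arg(family, modelFamilies())
  classes <- sort(unique(y))
  if (length(classes) < 2L) validationError("need at least two classes")
  x <- as.matrix(x)
  fit <- withSeed(seed, switch(family,
    xgboost = .fitXgb(x, y, classes, config),
    randomForest = .fitRf(x, y, classes, config),
    adaboost = .fitAda(x, y, classes, config),
    mlp = .fitMlp(x, y, classes, config)))
  structure(list(family = family, fit = fit, classes = classes,
                 config = config), class = "nucleoModel")
}

#' Class-probability predictions
#'
#' @param model a fitted [fitModel()] object.
#' @param x design matrix.
#' @return Numeric matrix, one column per class (named by class label).
#' @export
predictModel <- function(model, x) {
  x <- as.matrix(x)
  p <- switch(model$family,
    xgboost = .predXgb(model, x),
    randomForest = .predRf(model, x),
    adaboost = .predAda(model, x),
    mlp = .predMlp(model, x))
  colnames(p) <- as.character(model$classes)
  p
}

## -- xgboost ------------------------------------------------------------------

.fitXgb <- function(x, y, classes, cfg) {
  K <- length(classes)
  lab <- match(y, classes) - 1L
  params <- list(
    eta = cfg$eta %||% 0.3, max_depth = cfg$max_depth %||% 6L,
    min_child_weight = cfg$min_child_weight %||% 3,
    gamma = cfg$gamma %||% 0, subsample = cfg$subsample %||% 0.5,
    colsample_bytree = cfg$colsample_bytree %||% 0.5,
    lambda = cfg$lambda %||% 1, alpha = cfg$alpha %||% 0.01,
    nthread = 1L)
  if (K == 2L) {
    params$objective <- "binary:logistic"
  } else {
    params$objective <- "multi:softprob"
    params$num_class <- K
  }
  dtrain <- xgboost::xgb.DMatrix(x, label = lab)
  xgboost::xgb.train(params = params, data = dtrain,
                     nrounds = cfg$nrounds %||% 100L, verbose = 0)
}

.predXgb <- function(model, x) {
  K <- length(model$classes)
  p <- predict(model$fit, xgboost::xgb.DMatrix(x))
  if (K == 2L) cbind(1 - p, p) else matrix(p, ncol = K, byrow = TRUE)
}

## -- random forest ------------------------------------------------------------

.fitRf <- function(x, y, classes, cfg) {
  maxDepth <- cfg$max_depth %||% 30L
  randomForest::randomForest(
    x = x, y = factor(y, levels = classes),
    ntree = cfg$n_estimators %||% 100L,
    nodesize = cfg$min_samples_leaf %||% 2L,
    maxnodes = if (maxDepth < 20L) 2L^maxDepth else NULL)
}

.predRf <- function(model, x) {
  unname(predict(model$fit, x, type = "prob"))
}

## -- AdaBoost (SAMME / SAMME.R) on rpart trees --------------------------------

.adaControl <- function(cfg) {
  rpart::rpart.control(maxdepth = cfg$max_depth %||% 1L, cp = 0,
                       minsplit = 2L, minbucket = 1L, xval = 0L)
}

.fitAda <- function(x, y, classes, cfg) {
  M <- cfg$n_estimators %||% 200L
  lr <- cfg$learning_rate %||% 0.1
  algorithm <- cfg$algorithm %||% "SAMME.R"
  K <- length(classes)
  n <- nrow(x)
  yf <- factor(y, levels = classes)
  d <- data.frame(.y = yf, x, check.names = FALSE)
  w <- rep(1 / n, n)
  ctrl <- .adaControl(cfg)
  trees <- vector("list", M)
  alphas <- numeric(M)
  used <- 0L
  for (m in seq_len(M)) {
    fit <- rpart::rpart(.y ~ ., data = d, weights = w, method = "class",
                        control = ctrl)
    if (algorithm == "SAMME.R") {
      p <- pmin(pmax(predict(fit, d, type = "prob"), 1e-10), 1)
      # weight update with the symmetric class coding of SAMME.R
      yc <- matrix(-1 / (K - 1), n, K)
      yc[cbind(seq_len(n), as.integer(yf))] <- 1
      w <- w * exp(-lr * ((K - 1) / K) * rowSums(yc * log(p)))
      w <- w / sum(w)
      used <- used + 1L
      trees[[used]] <- fit
      alphas[used] <- 1
    } else {
      pred <- predict(fit, d, type = "class")
      miss <- pred != yf
      err <- sum(w[miss])
      if (err <= 0) {            # perfect weak learner: keep it, stop
        used <- used + 1L
        trees[[used]] <- fit
        alphas[used] <- 10
        break
      }
      if (err >= 1 - 1 / K) break  # no better than chance: stop
      a <- lr * (log((1 - err) / err) + log(K - 1))
      w <- w * exp(a * miss)
      w <- w / sum(w)
      used <- used + 1L
      trees[[used]] <- fit
      alphas[used] <- a
    }
  }
  list(trees = trees[seq_len(used)], alphas = alphas[seq_len(used)],
       algorithm = algorithm, lr = lr, K = K)
}

.predAda <- function(model, x) {
  f <- model$fit
  K <- f$K
  d <- as.data.frame(x)
  score <- matrix(0, nrow(x), K)
  for (m in seq_along(f$trees)) {
    if (f$algorithm == "SAMME.R") {
      p <- pmin(pmax(predict(f$trees[[m]], d, type = "prob"), 1e-10), 1)
      h <- (K - 1) * (log(p) - rowMeans(log(p)))
      score <- score + h
    } else {
      cl <- predict(f$trees[[m]], d, type = "class")
      score[cbind(seq_len(nrow(x)), as.integer(cl))] <-
        score[cbind(seq_len(nrow(x)), as.integer(cl))] + f$alphas[m]
    }
  }
  # softmax over the (scaled) additive scores
  s <- score / (max(length(f$trees), 1L) * (K - 1))
  e <- exp(s - apply(s, 1L, max))
  e / rowSums(e)
}

## -- feedforward network (nnet) -----------------------------------------------

.fitMlp <- function(x, y, classes, cfg) {
  mu <- colMeans(x)
  sdev <- apply(x, 2L, sd)
  sdev[sdev == 0] <- 1
  xs <- scale(x, mu, sdev)
  K <- length(classes)
  target <- nnet::class.ind(factor(y, levels = classes))
  fit <- nnet::nnet(xs, target, size = cfg$hidden_layer_sizes %||% 100L,
                    softmax = TRUE, maxit = cfg$max_iter %||% 200L,
                    decay = cfg$alpha %||% 0.1, trace = FALSE,
                    MaxNWts = 100000L)
  list(net = fit, mu = mu, sd = sdev, K = K)
}

.predMlp <- function(model, x) {
  f <- model$fit
  xs <- scale(x, f$mu, f$sd)
  p <- predict(f$net, xs)
  if (f$K == 2L && ncol(p) == 1L) p <- cbind(1 - p, p)
  unname(p)
}
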