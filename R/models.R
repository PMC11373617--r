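# The five classifier families behind one fit/score interface, their
# random-search spaces, and tuning.

.algorithms <- c("knn", "rf", "xgb", "svm", "lgr")

# Documented random-search spaces. Each entry is a function(seedless) drawing
# one configuration from the space; draws happen inside a seeded stream.
.sample_params <- function(algorithm) {
  switch(algorithm,
    knn = list(k = sample(c(3L, 5L, 7L, 9L, 11L), 1)),
    rf = list(num.trees = sample(c(100L, 200L, 300L), 1),
              mtry_frac = stats::runif(1, 0.2, 0.9),
              min.node.size = sample(c(1L, 3L, 5L), 1)),
    xgb = list(nrounds = sample(c(25L, 50L, 100L), 1),
               max_depth = sample(2:5, 1),
               eta = stats::runif(1, 0.05, 0.4),
               subsample = stats::runif(1, 0.6, 1)),
    svm = list(cost = 2^stats::runif(1, -3, 5),
               gamma = 2^stats::runif(1, -7, 1)),
    lgr = list(alpha = stats::runif(1, 0, 1),
               lambda = 10^stats::runif(1, -4, 0)),
    stop("unknown algorithm: ", algorithm))
}

#' Fit one classifier on a training block
#'
#' Thin wrapper putting the five supported families (kNN, random forest,
#' gradient-boosted trees, SVM, logistic regression) behind one interface.
#' Returns an object that [predict_scores()] maps to raw continuous scores
#' oriented so that larger means more likely high risk.
#'
#' @param algorithm one of `"knn"`, `"rf"`, `"xgb"`, `"svm"`, `"lgr"`.
#' @param x numeric feature matrix (train rows).
#' @param y factor labels with levels `c("low", "high")`.
#' @param params named list of hyperparameters for the family (see the
#'   random-search spaces in the package vignette); missing entries use
#'   defaults.
#' @param seed integer seed for stochastic learners.
#' @return object of class `omics_model`.
#' @export
fit_model <- function(algorithm, x, y, params = list(), seed = 1L) {
  algorithm <- match.arg(algorithm, .algorithms)
  x <- as.matrix(x)
  y <- factor(y, levels = c("low", "high"))
  if (length(unique(y)) < 2L) stop("degenerate training labels")
  fit <- with_seed(seed, switch(algorithm,
    knn = list(train_x = x, train_y = y, k = params$k %||% 5L),
    rf = {
      mtry <- max(1L, round((params$mtry_frac %||% 0.33) * ncol(x)))
      ranger::ranger(x = x, y = y, probability = TRUE,
                     num.trees = params$num.trees %||% 500L,
                     mtry = min(mtry, ncol(x)),
                     min.node.size = params$min.node.size %||% 1L,
                     num.threads = 1L, seed = seed)
    },
    xgb = xgboost::xgb.train(
      params = list(objective = "binary:logistic",
                    max_depth = params$max_depth %||% 3L,
                    eta = params$eta %||% 0.3,
                    subsample = params$subsample %||% 1,
                    nthread = 1L, seed = seed),
      data = xgboost::xgb.DMatrix(x, label = as.integer(y == "high"),
                                  nthread = 1L),
      nrounds = params$nrounds %||% 50L, verbose = 0),
    svm = e1071::svm(x = x, y = y, kernel = "radial",
                     cost = params$cost %||% 1,
                     gamma = params$gamma %||% (1 / ncol(x)),
                     scale = FALSE),
    lgr = glmnet::glmnet(x = x, y = y, family = "binomial",
                         alpha = params$alpha %||% 0.5,
                         lambda = params$lambda %||% 0.01)))
  structure(list(algorithm = algorithm, fit = fit, params = params,
                 features = colnames(x)),
            class = "omics_model")
}

#' Raw prediction scores of a fitted model
#'
#' @param model an `omics_model` from [fit_model()].
#' @param newx numeric matrix with the model's feature columns.
#' @return numeric vector of raw scores (larger = more likely high risk).
#' @export
predict_scores <- function(model, newx) {
  newx <- as.matrix(newx)[, model$features, drop = FALSE]
  switch(model$algorithm,
    knn = {
      pr <- class::knn(train = model$fit$train_x, test = newx,
                       cl = model$fit$train_y, k = model$fit$k, prob = TRUE)
      p <- attr(pr, "prob")
      ifelse(pr == "high", p, 1 - p)
    },
    rf = stats::predict(model$fit, data = newx, num.threads = 1L)$predictions[, "high"],
    xgb = stats::predict(model$fit, xgboost::xgb.DMatrix(newx, nthread = 1L)),
    svm = {
      dv <- attr(stats::predict(model$fit, newx, decision.values = TRUE),
                 "decision.values")
      # decision values are oriented toward the first class of the colname
      if (startsWith(colnames(dv)[1], "high")) as.numeric(dv) else -as.numeric(dv)
    },
    lgr = as.numeric(stats::predict(model$fit, newx, type = "response")))
}

#' Random-search hyperparameter tuning on inner validation splits
#'
#' Samples `budget` configurations from the family's search space (together
#' with the mRMR feature count when a grid is supplied), scores each by mean
#' AUC over stratified inner shuffle splits of the training fold, and refits
#' the best configuration on the full training fold. The inner-split
#' held-out predictions of the winning configuration are returned for
#' isotonic calibration, so the calibration map never sees training scores
#' of the model that produced them.
#'
#' @param algorithm model family.
#' @param x training feature matrix (already imputed and z-scored).
#' @param y training labels.
#' @param feature_order mRMR-ordered candidate feature names.
#' @param k_grid candidate selected-feature counts (first `k` of
#'   `feature_order`); a single value fixes `k`.
#' @param budget number of random-search draws (default 20).
#' @param inner_splits number of inner stratified shuffle splits (default 3).
#' @param inner_frac inner training fraction (default 0.75).
#' @param seed integer seed.
#' @return list: `model` (refit on full fold), `params`, `k`, `features`,
#'   `cal_scores`, `cal_labels` (held-out calibration material),
#'   `search_auc`.
#' @export
tune_and_train <- function(algorithm, x, y, feature_order,
                           k_grid = c(4L, 6L, 8L, 10L, 12L, 16L),
                           budget = 20L, inner_splits = 3L, inner_frac = 0.75,
                           seed = 1L) {
  x <- as.matrix(x)
  y <- factor(y, levels = c("low", "high"))
  if (length(unique(y)) < 2L) stop("degenerate training labels")
  k_grid <- k_grid[k_grid <= length(feature_order)]
  if (length(k_grid) == 0L) k_grid <- length(feature_order)
  inner <- make_folds(y, n_folds = inner_splits, train_frac = inner_frac,
                      seed = derive_seed(seed, 7L))
  draws <- with_seed(derive_seed(seed, 11L), {
    lapply(seq_len(budget), function(d)
      list(params = .sample_params(algorithm),
           k = k_grid[sample.int(length(k_grid), 1)]))
  })
  score_draw <- function(d, di) {
    feats <- feature_order[seq_len(d$k)]
    per <- lapply(seq_along(inner), function(s) {
      sp <- inner[[s]]
      m <- fit_model(algorithm, x[sp$train, feats, drop = FALSE], y[sp$train],
                     d$params, seed = derive_seed(seed, 100L + di * 10L + s))
      sc <- predict_scores(m, x[sp$test, feats, drop = FALSE])
      list(auc = .auc_midrank(sc, y[sp$test]), scores = sc, labels = y[sp$test])
    })
    list(auc = mean(vapply(per, `[[`, numeric(1), "auc")), per = per)
  }
  results <- lapply(seq_along(draws), function(di) score_draw(draws[[di]], di))
  aucs <- vapply(results, `[[`, numeric(1), "auc")
  best <- which.max(aucs)
  d <- draws[[best]]
  feats <- feature_order[seq_len(d$k)]
  model <- fit_model(algorithm, x[, feats, drop = FALSE], y, d$params,
                     seed = derive_seed(seed, 99L))
  cal <- results[[best]]$per
  list(model = model, params = d$params, k = d$k, features = feats,
       cal_scores = unlist(lapply(cal, `[[`, "scores")),
       cal_labels = factor(unlist(lapply(cal, function(p) as.character(p$labels))),
                           levels = c("low", "high")),
       search_auc = aucs[best])
}
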