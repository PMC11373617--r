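# The leakage-free Monte Carlo cross-validation experiment.

#' Pipeline configuration
#'
#' @param algorithm classifier family (`"knn"`, `"rf"`, `"xgb"`, `"svm"`,
#'   `"lgr"`).
#' @param n_folds Monte Carlo repetitions (default 100).
#' @param train_frac training fraction per fold (default 0.70).
#' @param imputation_k neighbors for kNN imputation (default 5).
#' @param mrmr_k_grid candidate selected-feature counts explored by random
#'   search (default `c(4, 6, 8, 10, 12, 16)`); a single value fixes the
#'   count.
#' @param search_budget random-search draws per fold (default 20).
#' @param inner_splits inner stratified shuffle splits for tuning (default
#'   3).
#' @param calibrate apply isotonic calibration (default `TRUE`).
#' @param threshold classification threshold on calibrated probabilities
#'   (default 0.5).
#' @param missing_threshold per-fold missingness exclusion level (default
#'   0.30, strict inequality).
#' @param seed master seed; every stochastic step derives its own seed from
#'   it, independent of the data.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(algorithm = "rf", n_folds = 100, train_frac = 0.70,
                            imputation_k = 5, mrmr_k_grid = c(4L, 6L, 8L, 10L, 12L, 16L),
                            search_budget = 20L, inner_splits = 3L,
                            calibrate = TRUE, threshold = 0.5,
                            missing_threshold = 0.30, seed = 1L) {
  structure(list(algorithm = match.arg(algorithm, .algorithms),
                 n_folds = check_count(n_folds, "n_folds"),
                 train_frac = check_fraction(train_frac, "train_frac"),
                 imputation_k = check_count(imputation_k, "imputation_k"),
                 mrmr_k_grid = as.integer(mrmr_k_grid),
                 search_budget = check_count(search_budget, "search_budget"),
                 inner_splits = check_count(inner_splits, "inner_splits"),
                 calibrate = isTRUE(calibrate),
                 threshold = check_fraction(threshold, "threshold"),
                 missing_threshold = check_fraction(missing_threshold, "missing_threshold"),
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

# One fold: filter -> impute -> z-score -> mRMR -> tune/train -> calibrate ->
# score the test partition. Everything is fitted on the training rows only.
run_fold <- function(features, labels, fold, config) {
  x <- as.matrix(features)
  tr <- fold$train; te <- fold$test
  # per-fold missingness filter on the training partition
  miss_rate <- colMeans(is.na(x[tr, , drop = FALSE]))
  keep <- miss_rate <= config$missing_threshold
  x <- x[, keep, drop = FALSE]
  imp <- knn_impute(x[tr, , drop = FALSE], x[te, , drop = FALSE],
                    k = config$imputation_k)
  zs <- suppressWarnings(zscore(imp$train, imp$test))
  # drop zero-variance training columns (uninformative after z-scoring)
  nz <- zs$params$sd > 0
  xtr <- zs$train[, nz, drop = FALSE]; xte <- zs$test[, nz, drop = FALSE]
  max_k <- min(max(config$mrmr_k_grid), ncol(xtr))
  order_feats <- mrmr_select(xtr, labels[tr], max_k)
  tt <- tune_and_train(config$algorithm, xtr, labels[tr], order_feats,
                       k_grid = config$mrmr_k_grid,
                       budget = config$search_budget,
                       inner_splits = config$inner_splits,
                       seed = derive_seed(config$seed, 50000L + fold$fold))
  raw_test <- predict_scores(tt$model, xte)
  if (config$calibrate) {
    cal <- suppressWarnings(calibrate(tt$cal_scores, tt$cal_labels))
    test_scores <- cal(raw_test)
  } else {
    test_scores <- raw_test
  }
  metrics <- evaluate(test_scores, labels[te], config$threshold)
  list(fold = fold$fold, selected = tt$features, params = tt$params,
       k = tt$k, scores = stats::setNames(test_scores, rownames(x)[te]),
       metrics = metrics, model = tt$model,
       test_x = xte, test_labels = labels[te],
       prep_params = list(kept = colnames(x),
                          impute = imp$params, zscore = zs$params))
}

#' Run the Monte Carlo cross-validation experiment
#'
#' Executes the full leakage-free pipeline on an assembled design matrix:
#' for each stratified 70/30 fold, the missingness filter, distance-weighted
#' kNN imputation, z-scoring, mRMR selection, random-search tuning of the
#' chosen classifier family, isotonic calibration and test-set scoring are
#' all fitted on the training partition only. Per-metric means with
#' percentile 95% confidence intervals and per-feature selection frequencies
#' are aggregated over folds.
#'
#' @param table an [assemble()]d `omics_table`.
#' @param config a [pipeline_config()].
#' @param categories optional character vector restricting the feature
#'   columns to given categories (e.g. `c("genomics", "pathomics")` for
#'   ablation runs); `NULL` uses all columns.
#' @return object of class `cv_summary`: list with `summary` (per-metric
#'   mean/CI data.frame), `selection_frequency`, `folds` (per-fold results),
#'   `failed` (error messages of failed folds), `config`.
#' @export
run_experiment <- function(table, config = pipeline_config(), categories = NULL) {
  stopifnot(inherits(table, "omics_table"), inherits(config, "pipeline_config"))
  feats <- table$features
  if (!is.null(categories)) {
    keep <- names(table$categories)[table$categories %in% categories]
    feats <- feats[, keep, drop = FALSE]
  }
  folds <- make_folds(table$labels, config$n_folds, config$train_frac,
                      seed = config$seed)
  results <- vector("list", length(folds)); errors <- character(0)
  for (i in seq_along(folds)) {
    results[[i]] <- tryCatch(run_fold(feats, table$labels, folds[[i]], config),
                             error = function(e) e)
    if (inherits(results[[i]], "error")) {
      errors <- c(errors, sprintf("fold %d: %s", i, conditionMessage(results[[i]])))
      results[[i]] <- NULL
    }
  }
  ok <- results[!vapply(results, is.null, logical(1))]
  if (length(errors) > 0.1 * length(folds))
    stop("more than 10% of folds failed:\n", paste(errors, collapse = "\n"))
  met <- do.call(rbind, lapply(ok, `[[`, "metrics"))
  summary_df <- data.frame(
    metric = colnames(met),
    mean = colMeans(met, na.rm = TRUE),
    ci_lower = apply(met, 2, stats::quantile, 0.025, na.rm = TRUE),
    ci_upper = apply(met, 2, stats::quantile, 0.975, na.rm = TRUE),
    row.names = NULL)
  sel <- table(unlist(lapply(ok, `[[`, "selected"))) / length(ok)
  sel <- sort(as.numeric(sel) |> stats::setNames(names(sel)), decreasing = TRUE)
  structure(list(summary = summary_df, selection_frequency = sel,
                 folds = ok, failed = errors, metrics_by_fold = met,
                 config = config),
            class = "cv_summary")
}

#' @export
print.cv_summary <- function(x, ...) {
  cat("<cv_summary> ", length(x$folds), " folds, algorithm ",
      x$config$algorithm, "\n", sep = "")
  df <- x$summary
  for (i in seq_len(nrow(df)))
    cat(sprintf("  %-4s %.3f (95%% CI %.3f-%.3f)\n", df$metric[i], df$mean[i],
                df$ci_lower[i], df$ci_upper[i]))
  invisible(x)
}

#' Fit the final whole-dataset model
#'
#' Runs the fold pipeline once on the entire cohort (missingness filter,
#' imputation, z-scoring, mRMR with a fixed selected-feature count, random
#' search) to produce the single model used for patient-level explanation —
#' the analogue of a final model refit on all patients after
#' cross-validated evaluation.
#'
#' @param table an `omics_table`.
#' @param config a [pipeline_config()].
#' @param k selected-feature count of the final model (default 8).
#' @return list: `model` (`omics_model`), `features`, `x` (the preprocessed
#'   design matrix), `labels`.
#' @export
fit_final_model <- function(table, config = pipeline_config(), k = 8L) {
  stopifnot(inherits(table, "omics_table"))
  x <- as.matrix(table$features)
  keep <- colMeans(is.na(x)) <= config$missing_threshold
  x <- x[, keep, drop = FALSE]
  imp <- knn_impute(x, NULL, k = config$imputation_k)
  zs <- suppressWarnings(zscore(imp$train))
  xz <- zs$train[, zs$params$sd > 0, drop = FALSE]
  k <- min(k, ncol(xz))
  order_feats <- mrmr_select(xz, table$labels, k)
  tt <- tune_and_train(config$algorithm, xz, table$labels, order_feats,
                       k_grid = k, budget = config$search_budget,
                       inner_splits = config$inner_splits,
                       seed = derive_seed(config$seed, 90000L))
  list(model = tt$model, features = tt$features, x = xz, labels = table$labels)
}

#' Permutation importance aggregated over cross-validation folds
#'
#' Computes test-partition permutation importance for every fold's fitted
#' model and averages per feature over folds; features a fold's model does
#' not use contribute importance 0 for that fold.
#'
#' @param cv a `cv_summary` from [run_experiment()].
#' @param n_repeats permutations per feature and fold (default 10).
#' @param seed integer seed.
#' @return data.frame with `feature`, `importance` (mean over folds), `sd`
#'   (between-fold SD), `n_folds_selected`, ranked by importance.
#' @export
importance_over_folds <- function(cv, n_repeats = 10, seed = 1L) {
  stopifnot(inherits(cv, "cv_summary"))
  all_feats <- sort(unique(unlist(lapply(cv$folds, function(f) colnames(f$test_x)))))
  per_fold <- vapply(seq_along(cv$folds), function(i) {
    f <- cv$folds[[i]]
    # only the model's own features can have nonzero importance
    imp <- permutation_importance(f$model,
                                  f$test_x[, f$model$features, drop = FALSE],
                                  f$test_labels, n_repeats = n_repeats,
                                  seed = derive_seed(seed, i))
    out <- stats::setNames(numeric(length(all_feats)), all_feats)
    out[imp$feature] <- imp$importance
    out
  }, numeric(length(all_feats)))
  sel_count <- vapply(all_feats, function(fe)
    sum(vapply(cv$folds, function(f) fe %in% f$model$features, logical(1))),
    numeric(1))
  res <- data.frame(feature = all_feats,
                    importance = rowMeans(per_fold),
                    sd = apply(per_fold, 1, stats::sd),
                    n_folds_selected = as.integer(sel_count),
                    row.names = NULL, stringsAsFactors = FALSE)
  res[order(-res$importance), , drop = FALSE]
}

#' Single-feature baseline over the same folds
#'
#' Evaluates one feature (by default bxISUP, the needle-biopsy grade) as the
#' score itself on the test partition of every fold, providing the clinical
#' comparator for the multiomics model.
#'
#' @param table an `omics_table`.
#' @param feature feature column to use as the raw score (default
#'   `"bxISUP"`).
#' @param config a [pipeline_config()] (folds and seed are reused; the
#'   classifier settings are ignored).
#' @return data.frame of per-fold metrics plus a `mean` attribute.
#' @export
baseline_single_feature <- function(table, feature = "bxISUP",
                                    config = pipeline_config()) {
  stopifnot(inherits(table, "omics_table"), feature %in% names(table$features))
  folds <- make_folds(table$labels, config$n_folds, config$train_frac,
                      seed = config$seed)
  v <- table$features[[feature]]
  met <- do.call(rbind, lapply(folds, function(f) {
    te <- f$test
    sc <- v[te]
    sc[is.na(sc)] <- stats::median(v[f$train], na.rm = TRUE)
    # the raw feature is the score; the clinical cut (grade >= 3 for bxISUP,
    # train median otherwise) is the classification threshold
    thr <- if (feature == "bxISUP") 3 else stats::median(v[f$train], na.rm = TRUE)
    evaluate(sc, table$labels[te], threshold = thr)
  }))
  met <- as.data.frame(met)
  attr(met, "mean") <- colMeans(met, na.rm = TRUE)
  met
}
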