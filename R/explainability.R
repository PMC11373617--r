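# Explainability: permutation importance, category aggregation, Monte Carlo
# Shapley values, and surrogate decision trees with fidelity measurement.

#' Permutation feature importance
#'
#' Importance of a feature is the drop in a test-set metric (AUC by default)
#' when that feature's column is randomly permuted, averaged over
#' `n_repeats` permutations. Features the model does not use are reported
#' with importance exactly 0 (permuting them cannot change predictions).
#'
#' @param model an `omics_model` (or any object accepted by `score_fun`).
#' @param x numeric test feature matrix (columns must cover the model's
#'   features; extra columns are scored 0).
#' @param y test labels (factor `low`/`high`).
#' @param n_repeats permutations per feature (default 10).
#' @param seed integer seed.
#' @param score_fun function(model, x) returning scores; defaults to
#'   [predict_scores()].
#' @return data.frame with `feature`, `importance` (mean metric drop), `sd`.
#' @export
permutation_importance <- function(model, x, y, n_repeats = 10, seed = 1L,
                                   score_fun = predict_scores) {
  x <- as.matrix(x)
  y <- factor(y, levels = c("low", "high"))
  if (length(unique(y)) < 2L) stop("both classes required in the test set")
  baseline <- .auc_midrank(score_fun(model, x), y)
  used <- if (inherits(model, "omics_model")) model$features else colnames(x)
  res <- with_seed(seed, {
    lapply(colnames(x), function(f) {
      if (!f %in% used) return(c(mean = 0, sd = 0))
      drops <- vapply(seq_len(n_repeats), function(r) {
        xp <- x
        xp[, f] <- sample(xp[, f])
        baseline - .auc_midrank(score_fun(model, xp), y)
      }, numeric(1))
      c(mean = mean(drops), sd = stats::sd(drops))
    })
  })
  data.frame(feature = colnames(x),
             importance = vapply(res, `[[`, numeric(1), "mean"),
             sd = vapply(res, `[[`, numeric(1), "sd"),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Aggregate per-feature importances into category means
#'
#' @param importances data.frame with `feature` and `importance` columns.
#' @param categories named character vector mapping feature to category
#'   (as in an `omics_table`).
#' @return data.frame of per-category unweighted mean importance, ranked.
#' @export
category_importance <- function(importances, categories) {
  cat <- categories[importances$feature]
  if (anyNA(cat)) stop("untagged feature(s): ",
                       paste(importances$feature[is.na(cat)], collapse = ", "))
  agg <- tapply(importances$importance, cat, mean)
  out <- data.frame(category = names(agg), mean_importance = as.numeric(agg),
                    n_features = as.integer(table(cat)[names(agg)]),
                    stringsAsFactors = FALSE)
  out[order(-out$mean_importance), , drop = FALSE]
}

#' Monte Carlo Shapley values for one patient
#'
#' Estimates per-feature Shapley values by permutation sampling against a
#' marginal background: for each sampled permutation and background row, the
#' marginal contribution of each feature is the change in model output when
#' that feature switches from the background value to the patient's value,
#' given the features before it in the permutation. The per-permutation
#' contributions telescope, so the estimated values sum exactly to
#' `f(patient) - mean(f(background rows sampled))`.
#'
#' @param model an `omics_model`, or a plain function mapping a feature
#'   matrix to scores (explained over the columns of `background`).
#' @param background numeric matrix of background rows (typically the
#'   training table).
#' @param patient numeric vector (or 1-row matrix) of the patient's
#'   features.
#' @param n_coalitions number of sampled permutations (must be at least
#'   twice the feature count).
#' @param seed integer seed.
#' @return named numeric vector of signed Shapley values, one per model
#'   feature, with attribute `baseline` (mean background prediction used).
#' @export
shapley_estimate <- function(model, background, patient, n_coalitions = 200L,
                             seed = 1L) {
  if (is.function(model)) {
    score_fun <- model
    feats <- colnames(as.matrix(background))
  } else {
    score_fun <- function(m) predict_scores(model, m)
    feats <- model$features
  }
  p <- length(feats)
  if (p == 0L) stop("background must have named feature columns")
  if (n_coalitions < 2L * p)
    stop("n_coalitions must be at least 2 * number of features")
  background <- as.matrix(background)[, feats, drop = FALSE]
  pm <- if (is.matrix(patient) || is.data.frame(patient)) {
    as.matrix(patient)
  } else {
    matrix(patient, nrow = 1, dimnames = list(NULL, names(patient)))
  }
  xpat <- as.numeric(pm[1, feats])
  phi <- stats::setNames(numeric(p), feats)
  base_acc <- 0
  with_seed(seed, {
    for (it in seq_len(n_coalitions)) {
      perm <- sample.int(p)
      cur <- background[sample.int(nrow(background), 1L), ]
      # rows 1..p+1: background, then cumulatively switching features to the
      # patient's values in permutation order; one batched prediction call
      rows <- matrix(cur, nrow = p + 1, ncol = p, byrow = TRUE,
                     dimnames = list(NULL, feats))
      for (s in seq_len(p)) rows[(s + 1):(p + 1), perm[s]] <- xpat[perm[s]]
      outs <- score_fun(rows)
      base_acc <- base_acc + outs[1]
      phi[feats[perm]] <- phi[feats[perm]] + diff(outs)
    }
  })
  phi <- phi / n_coalitions
  attr(phi, "baseline") <- base_acc / n_coalitions
  phi
}

#' Fit a surrogate decision tree to a reference model
#'
#' Trains a depth-limited CART tree on the reference model's predicted
#' labels, then measures fidelity — how faithfully the tree reproduces the
#' reference predictions — as the AUC of the tree's probability against the
#' reference predicted label on a held-out 30% split. The tree is also
#' rendered as a human-readable rule list (a simplified diagnostic
#' workflow).
#'
#' @param score_fun function(x) returning reference-model scores for a
#'   feature matrix (e.g. `function(x) predict_scores(model, x)`).
#' @param x numeric feature matrix covering the feature space.
#' @param max_depth maximum tree depth (default 3).
#' @param threshold reference score cut defining predicted labels (default
#'   0.5).
#' @param holdout_frac held-out fraction for fidelity (default 0.30).
#' @param seed integer seed for the fidelity split.
#' @return object of class `surrogate_tree`: list with `tree` (rpart),
#'   `fidelity_auc` (held-out), `fidelity_insample` (training rows;
#'   nondecreasing in `max_depth`), `rules` (character vector),
#'   `features_used`.
#' @export
fit_surrogate <- function(score_fun, x, max_depth = 3, threshold = 0.5,
                          holdout_frac = 0.30, seed = 1L) {
  x <- as.data.frame(x)
  ref_scores <- score_fun(as.matrix(x))
  ref_label <- factor(ifelse(ref_scores >= threshold, "high", "low"),
                      levels = c("low", "high"))
  if (length(unique(ref_label)) < 2L)
    stop("reference predictions are constant; no surrogate can be fitted")
  n <- nrow(x)
  train_idx <- with_seed(seed, {
    sort(unlist(lapply(split(seq_len(n), ref_label), function(idx) {
      sample(idx, max(1L, round((1 - holdout_frac) * length(idx))))
    }), use.names = FALSE))
  })
  test_idx <- setdiff(seq_len(n), train_idx)
  df <- cbind(.y = ref_label, x)
  names(df) <- make.names(names(df), unique = TRUE)
  fit <- rpart::rpart(.y ~ ., data = df[train_idx, , drop = FALSE],
                      method = "class",
                      control = rpart::rpart.control(maxdepth = max_depth,
                                                     cp = 0, minsplit = 4,
                                                     minbucket = 2, xval = 0))
  prob <- stats::predict(fit, df[test_idx, , drop = FALSE])[, "high"]
  fid <- .auc_midrank(prob, ref_label[test_idx])
  # in-sample fidelity measures representational capacity: with nested
  # greedy trees it is nondecreasing in max_depth, unlike the held-out
  # fidelity, which also reflects generalization noise
  prob_tr <- stats::predict(fit, df[train_idx, , drop = FALSE])[, "high"]
  fid_in <- .auc_midrank(prob_tr, ref_label[train_idx])
  used <- setdiff(unique(as.character(fit$frame$var)), "<leaf>")
  # map sanitized names back to original feature names
  name_map <- stats::setNames(names(x), make.names(names(df), unique = TRUE)[-1])
  used_orig <- unname(name_map[used])
  structure(list(tree = fit, fidelity_auc = fid, fidelity_insample = fid_in,
                 rules = .tree_rules(fit, name_map),
                 features_used = used_orig, max_depth = max_depth),
            class = "surrogate_tree")
}

# Render root-to-leaf decision rules of an rpart classification tree.
.tree_rules <- function(fit, name_map = NULL) {
  fr <- fit$frame
  leaves <- which(fr$var == "<leaf>")
  paths <- rpart::path.rpart(fit, nodes = as.numeric(rownames(fr)[leaves]),
                             print.it = FALSE)
  vapply(seq_along(leaves), function(i) {
    cls <- attr(fit, "ylevels")[fr$yval[leaves[i]]]
    cond <- paths[[i]][-1]
    if (!is.null(name_map)) {
      for (nm in names(name_map))
        cond <- gsub(nm, name_map[[nm]], cond, fixed = TRUE)
    }
    paste0("IF ", if (length(cond)) paste(cond, collapse = " AND ") else "TRUE",
           " THEN predict ", cls)
  }, character(1))
}

#' @export
print.surrogate_tree <- function(x, ...) {
  cat("<surrogate_tree> depth <= ", x$max_depth, ", fidelity AUC ",
      sprintf("%.3f", x$fidelity_auc), "\n", sep = "")
  cat(paste0("  ", x$rules, collapse = "\n"), "\n")
  invisible(x)
}
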