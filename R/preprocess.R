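# Fold-wise preprocessing: distance-weighted kNN imputation and z-scoring.
# Every transform is fitted on the training partition only and applied
# unchanged to the test partition — the leakage contract of the pipeline.

#' Distance-weighted k-nearest-neighbor imputation
#'
#' Missing cells are filled with the inverse-distance-weighted mean of the
#' `k` nearest training rows (Euclidean distance over the dimensions observed
#' in both rows). Because imputation runs before z-scoring, columns are
#' min-max scaled internally — with ranges fitted on the training block — so
#' no single column dominates the distance; imputed values are returned on
#' the original scale. Observed values are never modified, and test rows are
#' imputed strictly against training neighbors.
#'
#' @param train,test numeric matrices/data.frames with identical columns
#'   (`test` may be `NULL`).
#' @param k neighbor count (default 5).
#' @return list `train`, `test` (completed numeric matrices) and `params`
#'   (the fitted column ranges and training column means).
#' @export
knn_impute <- function(train, test = NULL, k = 5) {
  train <- as.matrix(train)
  if (nrow(train) < k) stop("training block must have at least k rows")
  col_ok <- colSums(!is.na(train)) > 0
  if (any(!col_ok))
    stop("fully missing training column(s): ",
         paste(colnames(train)[!col_ok], collapse = ", "),
         " (apply the missingness filter first)")
  rng_min <- apply(train, 2, min, na.rm = TRUE)
  rng_max <- apply(train, 2, max, na.rm = TRUE)
  span <- pmax(rng_max - rng_min, .Machine$double.eps)
  col_means <- colMeans(train, na.rm = TRUE)
  scale_block <- function(m) sweep(sweep(m, 2, rng_min), 2, span, `/`)
  tr_s <- scale_block(train)
  fill <- function(block, block_s) {
    for (i in seq_len(nrow(block))) {
      miss <- which(is.na(block[i, ]))
      if (length(miss) == 0L) next
      for (j in miss) {
        donors <- which(!is.na(train[, j]))
        obs_dims <- which(!is.na(block_s[i, ]))
        if (length(obs_dims) == 0L) { block[i, j] <- col_means[j]; next }
        dvec <- vapply(donors, function(r) {
          shared <- obs_dims[!is.na(tr_s[r, obs_dims])]
          if (length(shared) == 0L) return(Inf)
          sqrt(sum((tr_s[r, shared] - block_s[i, shared])^2) / length(shared))
        }, numeric(1))
        ord <- order(dvec)[seq_len(min(k, length(donors)))]
        nd <- dvec[ord]; nv <- train[donors[ord], j]
        if (any(nd == 0)) {
          block[i, j] <- mean(nv[nd == 0])
        } else if (all(is.infinite(nd))) {
          block[i, j] <- col_means[j]
        } else {
          w <- 1 / nd[is.finite(nd)]
          block[i, j] <- sum(w * nv[is.finite(nd)]) / sum(w)
        }
      }
    }
    block
  }
  train_out <- fill(train, tr_s)
  test_out <- NULL
  if (!is.null(test)) {
    test <- as.matrix(test)
    stopifnot(identical(colnames(test), colnames(train)))
    test_out <- fill(test, scale_block(test))
  }
  list(train = train_out, test = test_out,
       params = list(k = k, range_min = rng_min, range_max = rng_max,
                     col_means = col_means))
}

#' Z-score standardization with train-fitted parameters
#'
#' Column means and standard deviations are estimated on the training block
#' (population SD, i.e. denominator `n`) and applied to both blocks.
#' Zero-variance training columns map to all-zeros with a warning.
#'
#' @param train,test numeric matrices with identical columns (`test` may be
#'   `NULL`).
#' @return list `train`, `test`, `params` (`mean`, `sd` per column).
#' @export
zscore <- function(train, test = NULL) {
  train <- as.matrix(train)
  if (nrow(train) < 2L) stop("need at least 2 training rows")
  mu <- colMeans(train)
  sd_pop <- sqrt(colMeans(sweep(train, 2, mu)^2))
  zero <- sd_pop == 0
  if (any(zero))
    warning("zero-variance column(s) mapped to 0: ",
            paste(colnames(train)[zero], collapse = ", "))
  sd_use <- ifelse(zero, 1, sd_pop)
  tf <- function(m) sweep(sweep(m, 2, mu), 2, sd_use, `/`)
  out_train <- tf(train)
  out_train[, zero] <- 0
  out_test <- NULL
  if (!is.null(test)) {
    test <- as.matrix(test)
    out_test <- tf(test)
    out_test[, zero] <- 0
  }
  list(train = out_train, test = out_test,
       params = list(mean = mu, sd = sd_pop))
}
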