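# Stratified Monte Carlo fold construction.

#' Stratified Monte Carlo cross-validation folds
#'
#' Draws `n_folds` independent stratified random train/test splits. Per-class
#' training counts are the class sizes times `train_frac` rounded to the
#' nearest integer; if their sum misses the rounded overall training size,
#' the larger class is adjusted by one. Sampling within a fold is without
#' replacement; folds are drawn independently of each other.
#'
#' @param labels factor of binary class labels (levels `low`, `high`), named
#'   by or aligned with patient ids.
#' @param n_folds number of Monte Carlo repetitions (default 100).
#' @param train_frac training fraction (default 0.70).
#' @param seed master seed; fold `i` uses a seed derived from it.
#' @return list of fold specs: `fold`, `train` (indices), `test`, `seed`.
#' @export
make_folds <- function(labels, n_folds = 100, train_frac = 0.70, seed = 1L) {
  labels <- as.factor(labels)
  tab <- table(labels)
  if (length(tab) != 2L || any(tab < 2L))
    stop("both classes must be present with at least 2 members")
  n <- length(labels)
  n_train_total <- round(train_frac * n)
  per_class <- round(train_frac * as.numeric(tab))
  gap <- n_train_total - sum(per_class)
  if (gap != 0L) {
    larger <- which.max(tab)
    per_class[larger] <- per_class[larger] + gap
  }
  if (any(per_class < 1L) || any(per_class >= as.numeric(tab)))
    stop("train_frac leaves a class without train or test members")
  idx_by_class <- split(seq_len(n), labels)
  lapply(seq_len(n_folds), function(f) {
    fs <- derive_seed(seed, f)
    train <- with_seed(fs, {
      sort(unlist(lapply(seq_along(idx_by_class), function(k) {
        sample(idx_by_class[[k]], per_class[k])
      }), use.names = FALSE))
    })
    list(fold = f, train = train, test = setdiff(seq_len(n), train), seed = fs)
  })
}
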