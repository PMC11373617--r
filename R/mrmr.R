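# Minimum-redundancy maximum-relevance feature selection (MID criterion).

# Equal-frequency discretization into nb bins; returns integer codes.
# Features with at most nb distinct values are already discrete: their values
# become the categories directly (quantile breaks would merge them into a
# single degenerate bin and zero out their information content).
.discretize_ef <- function(x, nb) {
  ux <- sort(unique(x))
  if (length(ux) <= nb) return(match(x, ux))
  qs <- unique(stats::quantile(x, probs = seq(0, 1, length.out = nb + 1),
                               type = 7, names = FALSE))
  if (length(qs) < 2L) return(rep(1L, length(x)))
  as.integer(cut(x, breaks = qs, include.lowest = TRUE))
}

# Mutual information (nats) between two integer-coded vectors (codes >= 1).
.mutual_info <- function(a, b) {
  na <- max(a); nb <- max(b)
  p <- matrix(tabulate((a - 1L) * nb + b, nbins = na * nb), na, nb,
              byrow = TRUE) / length(a)
  pa <- rowSums(p); pb <- colSums(p)
  nz <- p > 0
  sum(p[nz] * log(p[nz] / outer(pa, pb)[nz]))
}

#' mRMR feature selection
#'
#' Greedy forward selection under the mutual-information-difference (MID)
#' criterion: at each step the feature maximizing
#' `relevance - redundancy` is added, where relevance is the mutual
#' information between the (discretized) feature and the label and redundancy
#' is the mean mutual information with the already-selected features.
#' Continuous features are discretized into `min(5, floor(n/5))`
#' equal-frequency bins. Selection is deterministic; ties break by column
#' order.
#'
#' @param x numeric matrix/data.frame of candidate features (train rows
#'   only).
#' @param y binary label factor/vector aligned with rows of `x`.
#' @param k number of features to select.
#' @return character vector of the selected feature names, in selection
#'   order.
#' @export
mrmr_select <- function(x, y, k) {
  x <- as.matrix(x)
  p <- ncol(x); n <- nrow(x)
  if (k > p) stop("k exceeds the number of candidate features")
  y <- as.integer(as.factor(y))
  if (length(unique(y)) != 2L) stop("labels must be binary")
  nb <- max(min(5L, floor(n / 5)), 2L)
  disc <- apply(x, 2, .discretize_ef, nb = nb)
  relevance <- vapply(seq_len(p), function(j) .mutual_info(disc[, j], y), numeric(1))
  selected <- integer(0)
  mi_cache <- matrix(NA_real_, p, p)
  for (step in seq_len(k)) {
    cand <- setdiff(seq_len(p), selected)
    crit <- vapply(cand, function(j) {
      red <- if (length(selected) == 0L) 0 else {
        mean(vapply(selected, function(s) {
          if (is.na(mi_cache[j, s])) {
            mi_cache[j, s] <<- .mutual_info(disc[, j], disc[, s])
            mi_cache[s, j] <<- mi_cache[j, s]
          }
          mi_cache[j, s]
        }, numeric(1)))
      }
      relevance[j] - red
    }, numeric(1))
    best <- cand[which.max(crit)]  # which.max takes the first max: column-order ties
    selected <- c(selected, best)
  }
  colnames(x)[selected]
}
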