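# Classification metrics and isotonic probability calibration.

# AUC by the rank statistic with midrank tie handling.
.auc_midrank <- function(scores, labels) {
  labels <- factor(labels, levels = c("low", "high"))
  n1 <- sum(labels == "high"); n0 <- sum(labels == "low")
  if (n1 == 0L || n0 == 0L) return(NA_real_)
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == "high"]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Binary classification metrics
#'
#' AUC by the rank statistic (midrank ties), plus confusion-matrix metrics at
#' the given probability threshold. The positive class is `"high"`.
#'
#' @param scores numeric scores/probabilities in \[0, 1\].
#' @param labels factor with levels `c("low", "high")`.
#' @param threshold classification cutoff (default 0.5).
#' @return named vector: `AUC`, `ACC`, `SNS`, `SPC`, `PPV`, `NPV`.
#' @export
evaluate <- function(scores, labels, threshold = 0.5) {
  labels <- factor(labels, levels = c("low", "high"))
  if (length(unique(labels)) < 2L)
    stop("both classes must be present in the evaluation set")
  pred_high <- scores >= threshold
  tp <- sum(pred_high & labels == "high"); fn <- sum(!pred_high & labels == "high")
  tn <- sum(!pred_high & labels == "low"); fp <- sum(pred_high & labels == "low")
  c(AUC = .auc_midrank(scores, labels),
    ACC = (tp + tn) / length(labels),
    SNS = tp / (tp + fn),
    SPC = tn / (tn + fp),
    PPV = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
    NPV = if (tn + fn > 0) tn / (tn + fn) else NA_real_)
}

#' Isotonic probability calibration
#'
#' Fits a monotone nondecreasing map from raw classifier scores to \[0, 1\]
#' using isotonic regression of the binary outcome on the score, evaluated on
#' held-out calibration material. Prediction interpolates linearly between
#' the fitted knots and clamps outside the observed score range, so the rank
#' order of any score vector is preserved (and AUC is unchanged).
#'
#' @param raw_scores numeric calibration scores.
#' @param labels factor with levels `c("low", "high")` aligned with
#'   `raw_scores`.
#' @return function mapping raw scores to calibrated probabilities.
#' @export
calibrate <- function(raw_scores, labels) {
  labels <- factor(labels, levels = c("low", "high"))
  y <- as.numeric(labels == "high")
  if (length(unique(raw_scores)) < 2L) {
    warning("constant raw scores: calibration map is the identity (clamped to [0,1])")
    return(function(s) pmin(pmax(s, 0), 1))
  }
  ord <- order(raw_scores)
  xs <- raw_scores[ord]; ys <- y[ord]
  # pool tied x before isotonic regression
  ux <- unique(xs)
  uy <- vapply(ux, function(v) mean(ys[xs == v]), numeric(1))
  iso <- stats::isoreg(ux, uy)
  knots_x <- iso$x; knots_y <- iso$yf
  mid <- stats::median(knots_x); sc <- max(stats::mad(knots_x), 1e-6)
  function(s) {
    out <- stats::approx(knots_x, knots_y, xout = s, rule = 2, ties = "ordered")$y
    out <- pmin(pmax(out, 0), 1)
    # an infinitesimal strictly increasing component keeps the map injective
    # over the flat isotonic steps, so score ranks (and AUC) are preserved
    # exactly; the probabilities themselves change by < 1e-9
    eps <- 1e-9
    out * (1 - eps) + eps * stats::plogis((s - mid) / sc)
  }
}
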