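# Immunohistochemistry H-scores and Gleason/ISUP label handling.

#' Modified H-score of one tissue core
#'
#' Combines the percentages of weakly, moderately and strongly stained cells
#' into the modified H-score
#' \deqn{H = 1\cdot\%_{weak} + 2\cdot\%_{moderate} + 3\cdot\%_{strong},}
#' ranging from 0 (no staining) to 300 (100% strongly stained cells). The
#' unstained fraction (100 minus the three percentages) carries weight 0.
#'
#' @param pct_weak,pct_moderate,pct_strong percentages in \[0, 100\]; their sum
#'   must not exceed 100. Vectorized over cores.
#' @return numeric H-score(s) in \[0, 300\].
#' @examples
#' h_score(0, 0, 100)   # 300
#' h_score(50, 30, 20)  # 170
#' @export
h_score <- function(pct_weak, pct_moderate, pct_strong) {
  p <- cbind(pct_weak, pct_moderate, pct_strong)
  if (any(!is.finite(p)) || any(p < 0) || any(p > 100))
    stop("staining percentages must be finite values in [0, 100]")
  if (any(rowSums(p) > 100 + 1e-9))
    stop("staining percentages of a core must sum to at most 100")
  as.numeric(p %*% c(1, 2, 3))
}

#' Aggregate per-core H-scores of one patient and marker
#'
#' Tumor cores (typically three per patient) are summarized by their mean and
#' maximum H-score; normal cores are excluded. Cores with missing percentages
#' are dropped before aggregation. With no usable tumor core both summaries
#' are `NA` and the feature enters downstream imputation.
#'
#' @param cores data.frame with columns `core_type` (`"tumor"`/`"normal"`),
#'   `pct_weak`, `pct_moderate`, `pct_strong` for one patient and one marker.
#' @return named numeric vector `c(h_avg =, h_max =)`.
#' @export
aggregate_marker <- function(cores) {
  stopifnot(is.data.frame(cores),
            all(c("core_type", "pct_weak", "pct_moderate", "pct_strong") %in% names(cores)))
  tum <- cores[cores$core_type == "tumor", , drop = FALSE]
  ok <- stats::complete.cases(tum[, c("pct_weak", "pct_moderate", "pct_strong")])
  tum <- tum[ok, , drop = FALSE]
  if (nrow(tum) == 0L) return(c(h_avg = NA_real_, h_max = NA_real_))
  h <- h_score(tum$pct_weak, tum$pct_moderate, tum$pct_strong)
  c(h_avg = mean(h), h_max = max(h))
}

#' Map Gleason patterns to the ISUP grade group
#'
#' Grade groups: 3+3 -> 1; 3+4 -> 2; 4+3 -> 3; Gleason score 8
#' (4+4, 3+5, 5+3) -> 4; score 9-10 -> 5.
#'
#' @param primary,secondary Gleason architectural patterns, each in `{3,4,5}`.
#'   Vectorized.
#' @return integer ISUP grade group(s) in `1:5`.
#' @export
gs_to_isup <- function(primary, secondary) {
  if (length(primary) != length(secondary))
    stop("primary and secondary patterns must have equal length")
  if (any(!primary %in% 3:5) || any(!secondary %in% 3:5))
    stop("Gleason patterns must be 3, 4 or 5")
  s <- primary + secondary
  out <- integer(length(s))
  out[s == 6] <- 1L
  out[primary == 3 & secondary == 4] <- 2L
  out[primary == 4 & secondary == 3] <- 3L
  out[s == 8] <- 4L
  out[s >= 9] <- 5L
  out
}

#' Binarize ISUP grade into the whole-mount risk group
#'
#' High risk is ISUP grade group >= 3, low risk is < 3.
#'
#' @param grade integer ISUP grade(s) in `1:5`.
#' @return factor with levels `c("low", "high")`; positive class is `"high"`.
#' @export
binarize_isup <- function(grade) {
  if (any(!grade %in% 1:5)) stop("ISUP grade must be in 1..5")
  factor(ifelse(grade >= 3, "high", "low"), levels = c("low", "high"))
}

#' Per-patient, per-marker pathomics feature block
#'
#' Computes `ihc::<marker>::avg` and `ihc::<marker>::max` H-score columns from
#' a long table of cores. An optional extra column carrying the TMA-core ISUP
#' grade (grade group of the highest-grade tumor core) can be appended so the
#' block matches a 2*n_markers + 1 column layout.
#'
#' @param ihc data.frame with columns `patient_id`, `marker`, `core_type`,
#'   `pct_weak`, `pct_moderate`, `pct_strong`; optionally `primary`,
#'   `secondary` Gleason patterns of tumor cores when `tma_grade_column` is
#'   `TRUE`.
#' @param patients character vector fixing row order; defaults to the patients
#'   present in `ihc`.
#' @param tma_grade_column append the `ihc::tma_isup` column (default `TRUE`).
#' @return data.frame with one row per patient, first column `patient_id`.
#' @export
pathomics_block <- function(ihc, patients = NULL, tma_grade_column = TRUE) {
  stopifnot(is.data.frame(ihc))
  patients <- patients %||% unique(ihc$patient_id)
  markers <- sort(unique(ihc$marker))
  out <- data.frame(patient_id = patients, stringsAsFactors = FALSE)
  for (m in markers) {
    agg <- t(vapply(patients, function(p) {
      aggregate_marker(ihc[ihc$patient_id == p & ihc$marker == m, , drop = FALSE])
    }, numeric(2)))
    out[[paste0("ihc::", m, "::avg")]] <- agg[, "h_avg"]
    out[[paste0("ihc::", m, "::max")]] <- agg[, "h_max"]
  }
  if (tma_grade_column) {
    has_gs <- all(c("primary", "secondary") %in% names(ihc))
    out[["ihc::tma_isup"]] <- vapply(patients, function(p) {
      if (!has_gs) return(NA_real_)
      tum <- ihc[ihc$patient_id == p & ihc$core_type == "tumor" &
                   !is.na(ihc$primary) & !is.na(ihc$secondary), , drop = FALSE]
      if (nrow(tum) == 0L) return(NA_real_)
      max(as.numeric(gs_to_isup(tum$primary, tum$secondary)))
    }, numeric(1))
  }
  rownames(out) <- NULL
  out
}
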