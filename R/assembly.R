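# Assembly of the category-tagged design matrix and the missingness filter.

#' Assemble the multiomics design matrix
#'
#' Joins the per-block feature tables on `patient_id` into one table whose
#' columns carry category tags (`clinical`, `radiomics`, `genomics`,
#' `pathomics`, `bxISUP`), aligned with the label vector. Patients absent
#' from a block keep their row and receive missing values for that block's
#' columns.
#'
#' @param clinical,radiomics,genomics,pathomics data.frames with a
#'   `patient_id` column followed by feature columns; any may be `NULL` to
#'   omit the block.
#' @param labels data.frame with `patient_id`, `bx_isup` and `risk` (factor
#'   `low`/`high`) columns; defines the patient universe and row order.
#' @return object of class `omics_table`: list with `features` (data.frame,
#'   rownames = patient ids), `categories` (named character vector), `labels`
#'   (factor), `bx_isup` (numeric), `patients`.
#' @export
assemble <- function(clinical = NULL, radiomics = NULL, genomics = NULL,
                     pathomics = NULL, labels) {
  stopifnot(is.data.frame(labels),
            all(c("patient_id", "bx_isup", "risk") %in% names(labels)))
  if (anyDuplicated(labels$patient_id)) stop("duplicate patient ids in labels")
  patients <- labels$patient_id
  blocks <- list(clinical = clinical, radiomics = radiomics,
                 genomics = genomics, pathomics = pathomics)
  blocks <- blocks[!vapply(blocks, is.null, logical(1))]
  present <- lapply(blocks, function(b) b$patient_id)
  if (length(blocks) && length(Reduce(intersect, c(present, list(patients)))) == 0L)
    stop("no patient appears in both the labels and the feature blocks")
  feat <- data.frame(row.names = patients)
  categories <- character(0)
  for (cat in names(blocks)) {
    b <- blocks[[cat]]
    if (anyDuplicated(b$patient_id)) stop("duplicate patient ids in ", cat, " block")
    cols <- setdiff(names(b), "patient_id")
    idx <- match(patients, b$patient_id)
    for (cl in cols) {
      if (cl %in% names(feat)) stop("duplicate feature column: ", cl)
      feat[[cl]] <- as.numeric(b[[cl]])[idx]
      categories[cl] <- cat
    }
  }
  feat[["bxISUP"]] <- as.numeric(labels$bx_isup)
  categories["bxISUP"] <- "bxISUP"
  structure(list(features = feat, categories = categories,
                 labels = factor(labels$risk, levels = c("low", "high")),
                 bx_isup = as.numeric(labels$bx_isup), patients = patients),
            class = "omics_table")
}

#' @export
print.omics_table <- function(x, ...) {
  cat("<omics_table> ", length(x$patients), " patients x ",
      ncol(x$features), " features (",
      paste(names(table(x$categories)), table(x$categories),
            sep = ": ", collapse = ", "), ")\n", sep = "")
  invisible(x)
}

#' Exclude features with excessive missingness
#'
#' Drops feature columns whose fraction of missing values strictly exceeds
#' `threshold` (default 0.30). Rows are never dropped. Inside cross-validation
#' the same rule is applied per fold on the training partition; this
#' whole-table version exists for dataset-level reporting.
#'
#' @param table an [assemble()]d `omics_table`.
#' @param threshold maximum tolerated missing fraction (default 0.30).
#' @return list with `table` (filtered `omics_table`) and `report`
#'   (data.frame of dropped columns and their missing rates).
#' @export
missingness_filter <- function(table, threshold = 0.30) {
  stopifnot(inherits(table, "omics_table"))
  rates <- vapply(table$features, function(col) mean(is.na(col)), numeric(1))
  drop <- rates > threshold
  report <- data.frame(feature = names(rates)[drop],
                       category = unname(table$categories[names(rates)[drop]]),
                       missing_rate = unname(rates[drop]),
                       stringsAsFactors = FALSE)
  table$features <- table$features[, !drop, drop = FALSE]
  table$categories <- table$categories[names(table$features)]
  list(table = table, report = report[order(-report$missing_rate), , drop = FALSE])
}

#' Build the full design matrix of a synthetic cohort
#'
#' Convenience wrapper running the genomics and pathomics feature engines on
#' a generated cohort and assembling all blocks with the labels.
#'
#' @param cohort a [generate_cohort()] result.
#' @return an `omics_table`.
#' @export
cohort_design_matrix <- function(cohort) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  gen <- genomics_block(cohort$variant_tables, cohort$cnv_tables,
                        cohort$sequenced_regions, cohort$gene_sets)
  pat <- pathomics_block(cohort$ihc_cores, patients = cohort$patients)
  assemble(clinical = cohort$clinical, radiomics = cohort$radiomics,
           genomics = gen, pathomics = pat, labels = cohort$labels)
}
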