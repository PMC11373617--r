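# Variant-to-pathway genomics features: pathogenicity metascore, gene- and
# pathway-level genetic disruption, tumor mutational burden, CNV burden.

#' Cohort-wise min-max normalization of CADD scores
#'
#' CADD is unbounded and is mapped onto \[0, 1\] over all variants of the
#' cohort before entering the metascore; EVE and PolyPhen already live on
#' \[0, 1\] and are used unchanged. If all non-missing values coincide the
#' range is degenerate and every value maps to 0. Missing values stay missing.
#'
#' @param cadd numeric vector of raw CADD scores across the whole cohort.
#' @return numeric vector of the same length in \[0, 1\] (NA preserved).
#' @export
normalize_cadd <- function(cadd) {
  obs <- cadd[!is.na(cadd)]
  if (length(obs) == 0L) stop("all CADD values are missing; nothing to normalize")
  rng <- range(obs)
  if (rng[1] == rng[2]) return(ifelse(is.na(cadd), NA_real_, 0))
  (cadd - rng[1]) / (rng[2] - rng[1])
}

#' Per-variant pathogenicity metascore
#'
#' The metascore of a variant is the unweighted mean of its available
#' pathogenicity scores: EVE and PolyPhen as-is, CADD after cohort-level
#' min-max normalization (see [normalize_cadd()]). Variants with no score at
#' all are unscorable: their metascore is `NA` and a warning is emitted; they
#' are excluded from disruption scores but still count toward TMB.
#'
#' @param eve,polyphen numeric vectors in \[0, 1\], `NA` allowed.
#' @param cadd_norm numeric vector of normalized CADD values in \[0, 1\].
#' @return numeric vector of metascores in \[0, 1\] (`NA` for unscorable
#'   variants).
#' @export
variant_metascore <- function(eve, cadd_norm, polyphen) {
  m <- cbind(eve, cadd_norm, polyphen)
  if (any(m < 0 | m > 1, na.rm = TRUE))
    stop("pathogenicity scores must lie in [0, 1] (normalize CADD first)")
  out <- rowMeans(m, na.rm = TRUE)
  none <- !is.finite(out)
  if (any(none)) {
    warning(sum(none), " variant(s) with no pathogenicity score excluded from disruption scoring")
    out[none] <- NA_real_
  }
  out
}

#' Gene-level genetic disruption of one patient
#'
#' The pathogenic genetic disruption of a gene is the sum of the pathogenicity
#' metascores of all of the patient's variants in that gene; genes without
#' variants score 0.
#'
#' @param variants data.frame with columns `gene` and `metascore` for one
#'   patient (unscorable variants may carry `NA` metascores; they are
#'   skipped).
#' @param genes optional character vector of genes to report (defaults to the
#'   mutated genes present).
#' @return named numeric vector of disruption scores, one per gene.
#' @export
gene_disruption <- function(variants, genes = NULL) {
  stopifnot(is.data.frame(variants), all(c("gene", "metascore") %in% names(variants)))
  v <- variants[!is.na(variants$metascore), , drop = FALSE]
  sums <- if (nrow(v)) tapply(v$metascore, v$gene, sum) else numeric(0)
  genes <- genes %||% names(sums)
  out <- stats::setNames(numeric(length(genes)), genes)
  hit <- intersect(genes, names(sums))
  out[hit] <- sums[hit]
  out
}

#' Pathway-level genetic disruption
#'
#' The disruption of a pathway is the sum of gene-level disruption over its
#' member genes. Genes the patient does not carry variants in contribute 0; a
#' gene belonging to several pathways contributes to each of them.
#'
#' @param gene_scores named numeric vector from [gene_disruption()].
#' @param catalog named list mapping pathway id to a character vector of gene
#'   symbols (see [read_gmt()]).
#' @return named numeric vector, one disruption score per pathway.
#' @export
pathway_disruption <- function(gene_scores, catalog) {
  stopifnot(is.list(catalog), length(catalog) > 0L, !is.null(names(catalog)))
  if (any(!nzchar(names(catalog)))) stop("pathway ids must be non-empty")
  vapply(catalog, function(genes) sum(gene_scores[intersect(genes, names(gene_scores))]),
         numeric(1))
}

#' Tumor mutational burden
#'
#' TMB is the number of identified somatic variants per million base pairs of
#' sequenced territory. All variants count, scorable or not.
#'
#' @param n_variants variant count (>= 0).
#' @param sequenced_size total sequenced territory in base pairs (> 0).
#' @return TMB in variants per megabase.
#' @export
compute_tmb <- function(n_variants, sequenced_size) {
  if (!is.numeric(sequenced_size) || sequenced_size <= 0)
    stop("sequenced_size must be a positive number of base pairs")
  if (n_variants < 0) stop("n_variants must be >= 0")
  n_variants / (sequenced_size / 1e6)
}

# 0-based half-open intervals -> IRanges (1-based closed).
.iranges_from_bed <- function(df) {
  IRanges::IRanges(start = df$start + 1L, end = df$end)
}

#' Copy-number-variant burden
#'
#' The CNV burden is the fraction of the sequenced territory covered by CNV
#' segments: overlapping segments are merged, intersected with the union of
#' sequenced regions, and the covered width is divided by the total region
#' width, so the result is guaranteed to lie in \[0, 1\].
#'
#' @param segments,regions data.frames of 0-based half-open intervals with
#'   columns `start`, `end` (a `chrom` column, if present, is honored by
#'   computing per-chromosome overlaps).
#' @return burden in \[0, 1\].
#' @export
compute_cnv_burden <- function(segments, regions) {
  stopifnot(is.data.frame(regions), all(c("start", "end") %in% names(regions)))
  if (nrow(regions) == 0L) stop("sequenced regions must be non-empty")
  if (is.null(segments) || nrow(segments) == 0L) {
    reg <- IRanges::reduce(.iranges_from_bed(regions))
    return(0)
  }
  chroms_r <- if ("chrom" %in% names(regions)) regions$chrom else rep("*", nrow(regions))
  chroms_s <- if ("chrom" %in% names(segments)) segments$chrom else rep("*", nrow(segments))
  total <- 0; covered <- 0
  for (ch in unique(chroms_r)) {
    reg <- IRanges::reduce(.iranges_from_bed(regions[chroms_r == ch, , drop = FALSE]))
    total <- total + sum(IRanges::width(reg))
    seg_df <- segments[chroms_s == ch, , drop = FALSE]
    if (nrow(seg_df)) {
      seg <- IRanges::reduce(.iranges_from_bed(seg_df))
      covered <- covered + sum(IRanges::width(IRanges::intersect(seg, reg)))
    }
  }
  covered / total
}

#' Fraction of patients mutated per gene
#'
#' @param variant_tables named list (one data.frame per patient) each with a
#'   `gene` column; patients without variants contribute empty tables.
#' @return data.frame with columns `gene`, `n_patients`, `frequency`, sorted
#'   by decreasing frequency.
#' @export
mutated_gene_frequency <- function(variant_tables) {
  stopifnot(is.list(variant_tables), length(variant_tables) >= 1L)
  n <- length(variant_tables)
  per_patient <- lapply(variant_tables, function(v) unique(as.character(v$gene)))
  tab <- table(unlist(per_patient))
  out <- data.frame(gene = names(tab), n_patients = as.integer(tab),
                    frequency = as.numeric(tab) / n, stringsAsFactors = FALSE)
  out[order(-out$frequency, out$gene), , drop = FALSE]
}

#' Assemble the genomics feature block
#'
#' For every patient: one `pathway::<id>` disruption score per catalog
#' pathway, plus `TMB` and `CNV_burden` — n_pathways + 2 columns.
#' CADD is normalized once over the pooled cohort variants so every patient's
#' metascores share one scale.
#'
#' @param variant_tables named list of per-patient variant data.frames with
#'   columns `gene`, `eve`, `cadd`, `polyphen`.
#' @param cnv_tables named list of per-patient CNV segment data.frames
#'   (`start`, `end`, optional `chrom`).
#' @param regions sequenced-region intervals (`start`, `end`, optional
#'   `chrom`).
#' @param catalog pathway catalog as a named list of gene vectors.
#' @return data.frame, one row per patient, first column `patient_id`.
#' @export
genomics_block <- function(variant_tables, cnv_tables, regions, catalog) {
  patients <- names(variant_tables)
  stopifnot(!is.null(patients), identical(sort(patients), sort(names(cnv_tables))))
  pooled <- do.call(rbind, lapply(patients, function(p) {
    v <- variant_tables[[p]]
    if (is.null(v) || nrow(v) == 0L) return(NULL)
    cbind(patient_id = p, v[, c("gene", "eve", "cadd", "polyphen")])
  }))
  seq_size <- {
    chroms <- if ("chrom" %in% names(regions)) regions$chrom else rep("*", nrow(regions))
    sum(vapply(unique(chroms), function(ch)
      sum(IRanges::width(IRanges::reduce(.iranges_from_bed(regions[chroms == ch, , drop = FALSE])))),
      numeric(1)))
  }
  if (!is.null(pooled) && nrow(pooled)) {
    pooled$cadd_norm <- if (all(is.na(pooled$cadd))) NA_real_ else normalize_cadd(pooled$cadd)
    pooled$metascore <- suppressWarnings(
      variant_metascore(pooled$eve, pooled$cadd_norm, pooled$polyphen))
  }
  rows <- lapply(patients, function(p) {
    v <- if (is.null(pooled)) NULL else pooled[pooled$patient_id == p, , drop = FALSE]
    n_var <- if (is.null(v)) 0L else nrow(v)
    gs <- if (n_var) gene_disruption(v) else stats::setNames(numeric(0), character(0))
    dp <- pathway_disruption(gs, catalog)
    c(dp, TMB = compute_tmb(n_var, seq_size),
      CNV_burden = compute_cnv_burden(cnv_tables[[p]], regions))
  })
  mat <- do.call(rbind, rows)
  colnames(mat) <- c(paste0("pathway::", names(catalog)), "TMB", "CNV_burden")
  data.frame(patient_id = patients, mat, check.names = FALSE,
             stringsAsFactors = FALSE, row.names = NULL)
}
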