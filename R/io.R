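# Plain-text readers/writers for the cohort's on-disk formats.

#' Read a pathway catalog from a GMT file
#'
#' @param path GMT file (tab-separated: id, description, genes...).
#' @return named list mapping pathway id to gene symbols.
#' @export
read_gmt <- function(path) {
  fgsea::gmtPathways(path)
}

#' Write a pathway catalog to GMT
#'
#' @param catalog named list of gene-symbol vectors.
#' @param path output path.
#' @export
write_gmt <- function(catalog, path) {
  lines <- vapply(names(catalog), function(id)
    paste(c(id, id, catalog[[id]]), collapse = "\t"), character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read BED-style intervals (0-based half-open)
#'
#' @param path tab-separated file with columns chrom, start, end (no
#'   header).
#' @return data.frame with `chrom`, `start`, `end`.
#' @export
read_bed <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("chrom", "start", "end"),
                          colClasses = c("character", "numeric", "numeric"))
  df
}

#' Read a per-patient variant table
#'
#' @param path tab-separated file with header `patient, gene, eve, cadd,
#'   polyphen` (empty fields are missing scores).
#' @return data.frame.
#' @export
read_variants <- function(path) {
  utils::read.delim(path, na.strings = c("", "NA"))
}

#' Write a synthetic cohort to disk
#'
#' Emits the cohort in the pipeline's interchange formats: clinical CSV,
#' per-patient variant TSVs, CNV TSVs and a sequenced-regions BED, a gene-set
#' GMT, an IHC core CSV, a labels CSV, a radiomics-wide CSV, NIfTI volume and
#' mask pairs, and a JSON sidecar logging the generator configuration (seed
#' included).
#'
#' @param cohort a [generate_cohort()] result.
#' @param dir output directory.
#' @param volumes also write NIfTI volumes/masks (default `FALSE`; they are
#'   the largest artifacts).
#' @return invisibly, the output directory.
#' @export
write_cohort <- function(cohort, dir, volumes = FALSE) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(cohort$clinical, file.path(dir, "clinical.csv"), row.names = FALSE)
  utils::write.csv(cohort$radiomics, file.path(dir, "radiomics.csv"), row.names = FALSE)
  utils::write.csv(cohort$ihc_cores, file.path(dir, "ihc_cores.csv"), row.names = FALSE)
  utils::write.csv(cohort$labels, file.path(dir, "labels.csv"), row.names = FALSE)
  vdir <- file.path(dir, "variants"); dir.create(vdir, showWarnings = FALSE)
  cdir <- file.path(dir, "cnv"); dir.create(cdir, showWarnings = FALSE)
  for (p in cohort$patients) {
    v <- cohort$variant_tables[[p]]
    utils::write.table(cbind(patient = rep(p, nrow(v)), v),
                       file.path(vdir, paste0(p, ".tsv")), sep = "\t",
                       row.names = FALSE, quote = FALSE)
    utils::write.table(cohort$cnv_tables[[p]],
                       file.path(cdir, paste0(p, ".tsv")), sep = "\t",
                       row.names = FALSE, quote = FALSE)
  }
  utils::write.table(cohort$sequenced_regions,
                     file.path(dir, "sequenced_regions.bed"), sep = "\t",
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  write_gmt(cohort$gene_sets, file.path(dir, "gene_sets.gmt"))
  if (volumes) {
    ndir <- file.path(dir, "volumes"); dir.create(ndir, showWarnings = FALSE)
    for (i in seq_along(cohort$patients)) {
      p <- cohort$patients[i]
      vol <- cohort$suv_volumes[[i]]
      img <- RNifti::asNifti(vol$data)
      RNifti::pixdim(img) <- vol$spacing
      RNifti::writeNifti(img, file.path(ndir, paste0(p, "_suv.nii.gz")))
      msk <- RNifti::asNifti(cohort$voi_masks[[i]]$data * 1)
      RNifti::pixdim(msk) <- vol$spacing
      RNifti::writeNifti(msk, file.path(ndir, paste0(p, "_mask.nii.gz")))
    }
  }
  cfg <- cohort$config
  class(cfg) <- NULL
  cfg$effect_map <- as.list(cfg$effect_map)
  cfg$pathway_rate_boost <- as.list(cfg$pathway_rate_boost)
  jsonlite::write_json(cfg, file.path(dir, "config.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Read a volume/mask pair from NIfTI files
#'
#' @param volume_path,mask_path NIfTI files written by [write_cohort()].
#' @return list with `volume` ([suv_volume()]) and `mask` ([voi_mask()]).
#' @export
read_suv_nifti <- function(volume_path, mask_path) {
  img <- RNifti::readNifti(volume_path)
  msk <- RNifti::readNifti(mask_path)
  sp <- RNifti::pixdim(img)[1:3]
  list(volume = suv_volume(array(as.numeric(img), dim = dim(img)), sp),
       mask = voi_mask(array(as.numeric(msk) > 0.5, dim = dim(msk))))
}
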