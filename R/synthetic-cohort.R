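# Synthetic multiomics cohort generator.
#
# Emulates the statistical structure of the study data: a 65-patient prostate
# cancer cohort with whole-mount ISUP labels (~57% high risk), a biopsy-ISUP
# column derived through a confusion kernel, clinical features (some with
# ~35% missingness, as image-read parameters), a 113-column radiomics-wide
# table, per-patient somatic variant tables with EVE/CADD/PolyPhen scores,
# CNV segments over sequenced regions, a pathway catalog, IHC staining cores
# for 11 markers, and per-patient SUV phantoms. Labels are drawn first;
# features are generated conditional on the binary label so planted effect
# sizes are directly interpretable (difference in class means, in SD units).

# Clinical schema: 13 features; the image-read parameters default to ~35%
# missingness, mirroring lesion-level readings unavailable in a third of
# patients.
.clinical_schema <- function() {
  data.frame(
    name = c("clin::age", "clin::weight", "clin::height", "clin::bmi",
             "clin::psa_preop", "clin::preop_therapy", "clin::lesion_involvement",
             "clin::lesion_zone", "clin::extracapsular_extension",
             "clin::neurovascular_contact", "clin::lymph_node_infiltration",
             "clin::bone_metastasis", "clin::clinical_t_stage"),
    type = c("numeric", "numeric", "numeric", "numeric", "numeric",
             "categorical", "categorical", "categorical", "categorical",
             "categorical", "categorical", "categorical", "categorical"),
    n_levels = c(NA, NA, NA, NA, NA, 2, 3, 5, 2, 2, 2, 2, 7),
    image_read = c(FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, TRUE, TRUE,
                   TRUE, TRUE, TRUE, TRUE, TRUE),
    stringsAsFactors = FALSE)
}

.ihc_markers <- function() {
  c("PSA", "PSMA", "AR", "ERG", "PTEN", "Ki67", "p53", "RB1", "SYP", "CHGA", "CD56")
}

#' Configuration of a synthetic multiomics cohort
#'
#' Defaults reproduce the study's data structure: 65 patients, 57% high-risk
#' prevalence, 51 pathways (+TMB+CNV burden = 53 genomics columns), 11 IHC
#' markers (22 H-score columns + 1 TMA-grade column = 23 pathomics columns),
#' 13 clinical columns, a 113-column radiomics-wide block and 1 bxISUP
#' column — 203 features in total. Image-read clinical parameters default to
#' 35% missingness.
#'
#' @param n_patients cohort size (default 65).
#' @param prevalence_high expected fraction of high-risk (ISUP >= 3) patients
#'   (default 0.57).
#' @param n_pathways number of catalog pathways (default 51).
#' @param n_genes gene universe size (default 300).
#' @param genes_per_pathway pathway size (default 12).
#' @param n_markers number of IHC markers (default 11).
#' @param n_clinical number of clinical features (default 13; the built-in
#'   schema is truncated or NA-extended).
#' @param n_radiomics number of radiomics-wide columns (default 113: 107
#'   radiomics + 6 conventional SUV metrics).
#' @param missing_rate_map named list of per-category missingness fractions;
#'   categories `clinical_imaging`, `clinical_other`, `radiomics`,
#'   `pathomics`.
#' @param effect_map named numeric vector of standardized effect sizes
#'   (difference in class means, in SD units) keyed by feature name; IHC
#'   markers are keyed as `ihc::<marker>::max` etc. Unnamed features have
#'   effect 0 (label-independent).
#' @param bx_concordance probability that bxISUP equals whole-mount ISUP
#'   (default 0.70); discordant draws move one grade up or down.
#' @param bx_informative when `TRUE` (default) bxISUP is derived from the
#'   patient's own whole-mount grade through the concordance kernel; when
#'   `FALSE` it is drawn from the cohort's marginal grade distribution,
#'   independent of the label — the setting of a fully null cohort, since a
#'   biopsy-derived grade otherwise always carries label signal.
#' @param mutation_rate expected variants per gene per patient (default
#'   0.012, giving sparse mutation profiles).
#' @param pathway_rate_boost named numeric vector of multiplicative
#'   mutation-rate factors applied in the high-risk class to the genes of the
#'   named pathways (plants label signal in derived genomics features).
#' @param seed master seed.
#' @return object of class `cohort_config`.
#' @export
cohort_config <- function(n_patients = 65, prevalence_high = 0.57,
                          n_pathways = 51, n_genes = 300, genes_per_pathway = 12,
                          n_markers = 11, n_clinical = 13, n_radiomics = 113,
                          missing_rate_map = list(clinical_imaging = 0.35,
                                                  clinical_other = 0.02,
                                                  radiomics = 0,
                                                  pathomics = 0.05),
                          effect_map = numeric(0),
                          bx_concordance = 0.70,
                          bx_informative = TRUE,
                          mutation_rate = 0.012,
                          pathway_rate_boost = numeric(0),
                          seed = 1L) {
  cfg <- list(
    n_patients = check_count(n_patients, "n_patients"),
    prevalence_high = check_fraction(prevalence_high, "prevalence_high"),
    n_pathways = check_count(n_pathways, "n_pathways"),
    n_genes = check_count(n_genes, "n_genes"),
    genes_per_pathway = check_count(genes_per_pathway, "genes_per_pathway"),
    n_markers = check_count(n_markers, "n_markers"),
    n_clinical = check_count(n_clinical, "n_clinical"),
    n_radiomics = check_count(n_radiomics, "n_radiomics"),
    missing_rate_map = missing_rate_map,
    effect_map = effect_map,
    bx_concordance = check_fraction(bx_concordance, "bx_concordance"),
    bx_informative = isTRUE(bx_informative),
    mutation_rate = check_fraction(mutation_rate, "mutation_rate"),
    pathway_rate_boost = pathway_rate_boost,
    seed = as.integer(seed))
  for (nm in names(missing_rate_map)) check_fraction(missing_rate_map[[nm]], nm)
  if (cfg$n_markers > length(.ihc_markers()))
    stop_config("n_markers must be <= ", length(.ihc_markers()))
  structure(cfg, class = "cohort_config")
}

.effect_of <- function(cfg, name) {
  e <- cfg$effect_map[name]
  if (length(e) == 0L || is.na(e)) 0 else as.numeric(e)
}

# Draw a numeric feature with unit SD and class-mean difference `effect`.
.draw_numeric <- function(label_high, effect) {
  n <- length(label_high)
  stats::rnorm(n, mean = ifelse(label_high, effect / 2, -effect / 2), sd = 1)
}

#' Generate a synthetic multiomics cohort
#'
#' Labels are drawn first: whole-mount ISUP grades come from a categorical
#' distribution over 1..5 whose mass above the >= 3 cut equals
#' `prevalence_high`; Gleason patterns are back-filled from the grade and
#' bxISUP is sampled through the concordance kernel. Every feature block is
#' then generated conditional on the binary label, so a feature with planted
#' effect `e` differs between classes by `e` SD units in expectation and a
#' feature with effect 0 is label-independent.
#'
#' @param config a [cohort_config()].
#' @return object of class `synthetic_cohort`: list with `patients`,
#'   `labels` (patient_id, primary, secondary, isup, bx_isup, risk),
#'   `clinical`, `radiomics`, `ihc_cores`, `variant_tables`, `cnv_tables`,
#'   `sequenced_regions`, `gene_sets`, `suv_volumes`, `voi_masks`, `config`.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  cfg <- config
  with_seed(cfg$seed, {
    n <- cfg$n_patients
    patients <- sprintf("P%03d", seq_len(n))

    ## --- labels first -----------------------------------------------------
    p_high <- cfg$prevalence_high
    # split low mass over grades 1-2, high mass over 3-5
    grade_probs <- c(0.5 * (1 - p_high), 0.5 * (1 - p_high),
                     0.45 * p_high, 0.35 * p_high, 0.20 * p_high)
    isup <- sample(1:5, n, replace = TRUE, prob = grade_probs)
    patt <- rbind(c(3, 3), c(3, 4), c(4, 3), c(4, 4), c(4, 5))[isup, , drop = FALSE]
    high <- isup >= 3
    bx <- if (cfg$bx_informative) {
      vapply(isup, function(g) {
        if (stats::runif(1) < cfg$bx_concordance) return(g)
        cand <- intersect(c(g - 1, g + 1), 1:5)
        cand[sample.int(length(cand), 1)]
      }, numeric(1))
    } else {
      sample(1:5, n, replace = TRUE, prob = grade_probs)
    }
    labels <- data.frame(patient_id = patients,
                         primary = patt[, 1], secondary = patt[, 2],
                         isup = isup, bx_isup = as.integer(bx),
                         risk = binarize_isup(isup),
                         stringsAsFactors = FALSE)

    ## --- clinical ---------------------------------------------------------
    schema <- .clinical_schema()
    if (cfg$n_clinical <= nrow(schema)) {
      schema <- schema[seq_len(cfg$n_clinical), , drop = FALSE]
    } else {
      extra <- cfg$n_clinical - nrow(schema)
      schema <- rbind(schema, data.frame(
        name = paste0("clin::extra", seq_len(extra)), type = "numeric",
        n_levels = NA, image_read = FALSE))
    }
    clinical <- data.frame(patient_id = patients, stringsAsFactors = FALSE)
    for (r in seq_len(nrow(schema))) {
      nm <- schema$name[r]
      e <- .effect_of(cfg, nm)
      if (schema$type[r] == "numeric") {
        clinical[[nm]] <- .draw_numeric(high, e)
      } else {
        # integer-coded levels; planted effect shifts the level distribution
        k <- schema$n_levels[r]
        base <- rev(seq_len(k))  # lower levels more common
        shift <- seq_len(k)
        pr_low <- base / sum(base)
        w <- max(min(abs(e) / 2, 1), 0)
        pr_high <- (1 - w) * pr_low + w * shift / sum(shift)
        clinical[[nm]] <- ifelse(high,
                                 sample(seq_len(k), n, TRUE, pr_high),
                                 sample(seq_len(k), n, TRUE, pr_low))
      }
    }

    ## --- radiomics-wide (precomputed-table emulation) ---------------------
    rad_names <- .radiomics_wide_names(cfg$n_radiomics)
    radiomics <- data.frame(patient_id = patients, stringsAsFactors = FALSE)
    for (nm in rad_names) radiomics[[nm]] <- .draw_numeric(high, .effect_of(cfg, nm))

    ## --- IHC cores --------------------------------------------------------
    # core-level Gleason patterns carry the biopsy-kernel grade (the TMA
    # punch mimics a targeted biopsy), not the whole-mount truth
    bx_patt <- rbind(c(3, 3), c(3, 4), c(4, 3), c(4, 4), c(4, 5))[bx, , drop = FALSE]
    markers <- .ihc_markers()[seq_len(cfg$n_markers)]
    ihc <- do.call(rbind, lapply(seq_len(n), function(i) {
      do.call(rbind, lapply(markers, function(m) {
        e <- .effect_of(cfg, paste0("ihc::", m, "::max")) +
          .effect_of(cfg, paste0("ihc::", m, "::avg"))
        # target H-scores: mean 150, SD 45, class shift e*45
        h <- stats::rnorm(6, 150 + ifelse(high[i], e / 2, -e / 2) * 45, 45)
        h <- pmin(pmax(h, 0), 300)
        strong <- h / 3  # encode as pure strong staining
        data.frame(patient_id = patients[i], marker = m,
                   core_id = paste0("c", 1:6),
                   core_type = rep(c("tumor", "normal"), each = 3),
                   pct_weak = 0, pct_moderate = 0, pct_strong = strong,
                   primary = bx_patt[i, 1], secondary = bx_patt[i, 2],
                   stringsAsFactors = FALSE)
      }))
    }))

    ## --- genomics inputs --------------------------------------------------
    genes <- sprintf("GENE%04d", seq_len(cfg$n_genes))
    gene_sets <- stats::setNames(lapply(seq_len(cfg$n_pathways), function(k) {
      sample(genes, cfg$genes_per_pathway)
    }), sprintf("hsa%05d", seq_len(cfg$n_pathways)))
    regions <- data.frame(chrom = "chr1",
                          start = seq(0, by = 2e6, length.out = 20),
                          end = seq(0, by = 2e6, length.out = 20) + 1.5e6)
    rate <- rep(cfg$mutation_rate, cfg$n_genes)
    names(rate) <- genes
    boost <- rep(1, cfg$n_genes); names(boost) <- genes
    for (pw in names(cfg$pathway_rate_boost)) {
      if (pw %in% names(gene_sets))
        boost[gene_sets[[pw]]] <- pmax(boost[gene_sets[[pw]]],
                                       cfg$pathway_rate_boost[[pw]])
    }
    variant_tables <- stats::setNames(lapply(seq_len(n), function(i) {
      r <- if (high[i]) rate * boost else rate
      counts <- stats::rpois(cfg$n_genes, r)
      g <- rep(genes, counts)
      m <- length(g)
      if (m == 0L) {
        return(data.frame(gene = character(0), eve = numeric(0),
                          cadd = numeric(0), polyphen = numeric(0)))
      }
      data.frame(gene = g,
                 eve = stats::rbeta(m, 2, 2),
                 cadd = stats::rgamma(m, shape = 3, scale = 8),
                 polyphen = stats::rbeta(m, 2, 1.2),
                 stringsAsFactors = FALSE)
    }), patients)
    cnv_tables <- stats::setNames(lapply(seq_len(n), function(i) {
      k <- stats::rpois(1, 3)
      if (k == 0L) return(data.frame(chrom = character(0), start = numeric(0),
                                     end = numeric(0)))
      st <- sort(stats::runif(k, 0, 3.8e7))
      len <- stats::rexp(k, rate = 1 / 8e5)
      data.frame(chrom = "chr1", start = floor(st), end = floor(st + len))
    }), patients)

    ## --- SUV phantoms -----------------------------------------------------
    phantoms <- lapply(seq_len(n), function(i) {
      generate_suv_phantom(shape = c(24, 24, 24), spacing = c(2, 2, 2),
                           lesion_center = c(23, 23, 23),
                           lesion_radius_mm = stats::runif(1, 6, 12),
                           lesion_suv = stats::runif(1, 4, 12),
                           background_suv = 1, noise_sd = 0.2,
                           seed = derive_seed(cfg$seed, 1000L + i))
    })

    ## --- missingness ------------------------------------------------------
    mr <- cfg$missing_rate_map
    for (r in seq_len(nrow(schema))) {
      p_miss <- if (schema$image_read[r]) mr$clinical_imaging %||% 0 else mr$clinical_other %||% 0
      if (p_miss > 0) {
        hole <- stats::runif(n) < p_miss
        clinical[[schema$name[r]]][hole] <- NA
      }
    }
    if ((mr$radiomics %||% 0) > 0) {
      for (nm in rad_names) {
        hole <- stats::runif(n) < mr$radiomics
        radiomics[[nm]][hole] <- NA
      }
    }
    if ((mr$pathomics %||% 0) > 0) {
      hole <- stats::runif(nrow(ihc)) < mr$pathomics
      ihc$pct_strong[hole] <- NA
    }

    structure(list(patients = patients, labels = labels, clinical = clinical,
                   radiomics = radiomics, ihc_cores = ihc,
                   variant_tables = variant_tables, cnv_tables = cnv_tables,
                   sequenced_regions = regions, gene_sets = gene_sets,
                   suv_volumes = lapply(phantoms, `[[`, "volume"),
                   voi_masks = lapply(phantoms, `[[`, "mask"),
                   config = cfg),
              class = "synthetic_cohort")
  })
}

.radiomics_wide_names <- function(n_radiomics) {
  suv6 <- paste0("rad::suv::", c("SUVmin", "SUVmax", "SUVmean", "SUVpeak",
                                 "PSMA_TV", "TL_PSMA"))
  n_tex <- max(n_radiomics - 6L, 0L)
  fams <- c("firstorder", "glcm", "glrlm", "glszm", "gldm", "ngtdm", "shape")
  tex <- paste0("rad::", rep(fams, length.out = n_tex), "::f",
                sprintf("%03d", seq_len(n_tex)))
  c(suv6, tex)[seq_len(n_radiomics)]
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("<synthetic_cohort> ", length(x$patients), " patients, ",
      sum(x$labels$risk == "high"), " high-risk; ",
      length(x$gene_sets), " pathways, ",
      length(unique(x$ihc_cores$marker)), " IHC markers\n", sep = "")
  invisible(x)
}

#' Generate a spherical-lesion SUV phantom
#'
#' A 3D grid with constant background uptake, a spherical lesion of higher
#' uptake and additive Gaussian noise, plus the aligned binary VOI mask
#' (voxels whose centers lie within the lesion radius). Stands in for a PET
#' acquisition with a delineated lesion.
#'
#' @param shape integer length-3 voxel counts.
#' @param spacing numeric length-3 mm per axis.
#' @param lesion_center physical center in mm (length 3).
#' @param lesion_radius_mm sphere radius in mm.
#' @param lesion_suv,background_suv uptake values.
#' @param noise_sd SD of additive Gaussian noise (0 for noiseless).
#' @param seed integer seed.
#' @return list with `volume` ([suv_volume()]) and `mask` ([voi_mask()]).
#' @export
generate_suv_phantom <- function(shape, spacing, lesion_center, lesion_radius_mm,
                                 lesion_suv, background_suv = 1, noise_sd = 0,
                                 seed = 1L) {
  shape <- as.integer(shape); spacing <- as.numeric(spacing)
  stopifnot(length(shape) == 3L, length(spacing) == 3L, length(lesion_center) == 3L)
  extent <- (shape - 1L) * spacing
  if (any(lesion_center - lesion_radius_mm < 0) ||
      any(lesion_center + lesion_radius_mm > extent))
    stop("lesion does not fit inside the grid")
  ax <- lapply(1:3, function(i) (seq_len(shape[i]) - 1) * spacing[i])
  d2 <- array(0, dim = shape)
  for (k in seq_len(shape[3])) {
    d2[, , k] <- outer((ax[[1]] - lesion_center[1])^2,
                       (ax[[2]] - lesion_center[2])^2, `+`) +
      (ax[[3]][k] - lesion_center[3])^2
  }
  mask <- d2 <= lesion_radius_mm^2
  vol <- array(background_suv, dim = shape)
  vol[mask] <- lesion_suv
  if (noise_sd > 0)
    vol <- vol + with_seed(seed, array(stats::rnorm(prod(shape), 0, noise_sd),
                                       dim = shape))
  list(volume = suv_volume(vol, spacing), mask = voi_mask(mask))
}
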