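test_that("cohort generation is deterministic for a fixed seed", {
  a <- generate_cohort(cohort_config(n_patients = 20, seed = 5))
  b <- generate_cohort(cohort_config(n_patients = 20, seed = 5))
  expect_identical(a$labels, b$labels)
  expect_identical(a$clinical, b$clinical)
  expect_identical(a$radiomics, b$radiomics)
  expect_identical(a$variant_tables, b$variant_tables)
  expect_identical(a$suv_volumes[[3]]$data, b$suv_volumes[[3]]$data)
  c2 <- generate_cohort(cohort_config(n_patients = 20, seed = 6))
  expect_false(identical(a$labels$isup, c2$labels$isup))
})

test_that("label prevalence tracks the configured rate within sampling error", {
  co <- default_cohort()
  n_high <- sum(co$labels$risk == "high")
  # binomial 99.7% band around 0.57 * 65
  expect_lt(abs(n_high - 0.57 * 65), 3 * sqrt(65 * 0.57 * 0.43))
  expect_equal(co$labels$isup >= 3, co$labels$risk == "high")
  expect_equal(gs_to_isup(co$labels$primary, co$labels$secondary),
               as.integer(co$labels$isup))
})

test_that("invalid configurations are rejected", {
  expect_error(cohort_config(n_patients = 0), "integer >= 1")
  expect_error(cohort_config(prevalence_high = 1.2), "\\[0, 1\\]")
  expect_error(cohort_config(missing_rate_map = list(clinical_imaging = -0.1)),
               "\\[0, 1\\]")
})

test_that("zero-effect features are uncorrelated with the label", {
  # Monte Carlo: replicate null cohorts, point-biserial correlation of a
  # feature panel with the label stays within +/- 3/sqrt(n) on average
  reps <- 25
  feats <- c("clin::age", "clin::psa_preop", "rad::suv::SUVmax",
             "rad::glcm::f002", "ihc::PSA::max")
  cors <- matrix(NA_real_, reps, length(feats))
  for (r in seq_len(reps)) {
    co <- generate_cohort(cohort_config(n_patients = 40, seed = 2000 + r,
                                        bx_informative = FALSE,
                                        missing_rate_map = list()))
    blk <- pathomics_block(co$ihc_cores, patients = co$patients)
    y <- as.numeric(co$labels$risk == "high")
    vals <- cbind(co$clinical[, feats[1:2]], co$radiomics[, feats[3:4]],
                  blk[, feats[5]])
    cors[r, ] <- apply(vals, 2, function(v) cor(v, y))
  }
  # per-feature mean correlation within 3 SE of zero (SE = 1/sqrt(n*reps))
  expect_lt(max(abs(colMeans(cors))), 3 / sqrt(40 * reps))
  # and nearly all single-cohort correlations within the 3/sqrt(n) band
  expect_gt(mean(abs(cors) < 3 / sqrt(40)), 0.97)
})

test_that("planted effects shift class means by the stated SD units", {
  reps <- 25
  diffs <- numeric(reps)
  for (r in seq_len(reps)) {
    co <- generate_cohort(cohort_config(n_patients = 60, seed = 3000 + r,
                                        effect_map = c("rad::suv::SUVmean" = 1.5),
                                        missing_rate_map = list()))
    v <- co$radiomics[["rad::suv::SUVmean"]]
    y <- co$labels$risk
    diffs[r] <- mean(v[y == "high"]) - mean(v[y == "low"])
  }
  # features have unit SD by construction; SE of the mean difference ~ 0.26
  expect_lt(abs(mean(diffs) - 1.5), 3 * 0.27 / sqrt(reps))
})

test_that("realized missingness stays within 5 points of the configured rate", {
  co <- generate_cohort(cohort_config(
    seed = 77, missing_rate_map = list(clinical_imaging = 0.35,
                                       clinical_other = 0, radiomics = 0.10,
                                       pathomics = 0)))
  img_cols <- c("clin::lesion_involvement", "clin::lesion_zone",
                "clin::extracapsular_extension", "clin::neurovascular_contact",
                "clin::lymph_node_infiltration", "clin::bone_metastasis",
                "clin::clinical_t_stage")
  realized_img <- mean(is.na(as.matrix(co$clinical[, img_cols])))
  expect_lt(abs(realized_img - 0.35), 0.05)
  realized_rad <- mean(is.na(as.matrix(co$radiomics[, -1])))
  expect_lt(abs(realized_rad - 0.10), 0.05)
  expect_false(anyNA(co$clinical$`clin::age`))
})

test_that("bxISUP concordance follows the confusion kernel", {
  co <- generate_cohort(cohort_config(n_patients = 500, seed = 12,
                                      bx_concordance = 0.70))
  conc <- mean(co$labels$bx_isup == co$labels$isup)
  expect_lt(abs(conc - 0.70), 3 * sqrt(0.7 * 0.3 / 500))
  # discordant draws move exactly one grade
  disc <- abs(co$labels$bx_isup - co$labels$isup)
  expect_true(all(disc <= 1))
  # independent bxISUP carries no label information (chi-square sanity)
  co0 <- generate_cohort(cohort_config(n_patients = 500, seed = 13,
                                       bx_informative = FALSE))
  p <- suppressWarnings(chisq.test(table(co0$labels$bx_isup >= 3,
                                         co0$labels$risk)))$p.value
  expect_gt(p, 0.001)
})

test_that("every patient appears in every block", {
  co <- default_cohort()
  expect_equal(co$clinical$patient_id, co$patients)
  expect_equal(co$radiomics$patient_id, co$patients)
  expect_setequal(names(co$variant_tables), co$patients)
  expect_setequal(names(co$cnv_tables), co$patients)
  expect_setequal(unique(co$ihc_cores$patient_id), co$patients)
  expect_length(co$suv_volumes, length(co$patients))
  # 3 tumor + 3 normal cores per marker and patient
  cnt <- table(co$ihc_cores$patient_id, co$ihc_cores$marker)
  expect_true(all(cnt == 6))
})
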