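make_phantom <- function(noise = 0, suv = 5, seed = 1) {
  generate_suv_phantom(shape = c(12, 12, 12), spacing = c(2, 2, 2),
                       lesion_center = c(11, 11, 11), lesion_radius_mm = 6,
                       lesion_suv = suv, background_suv = 1, noise_sd = noise,
                       seed = seed)
}

test_that("noiseless phantoms have exact in-mask values and reproduce bitwise", {
  ph <- make_phantom()
  expect_true(all(ph$volume$data[ph$mask$data] == 5))
  expect_true(all(ph$volume$data[!ph$mask$data] == 1))
  a <- make_phantom(noise = 0.3, seed = 42)
  b <- make_phantom(noise = 0.3, seed = 42)
  expect_identical(a$volume$data, b$volume$data)
  expect_error(generate_suv_phantom(c(10, 10, 10), c(2, 2, 2), c(2, 2, 2),
                                    lesion_radius_mm = 8, lesion_suv = 5),
               "fit")
})

test_that("mask volume approximates the analytic sphere volume", {
  ph <- generate_suv_phantom(shape = c(24, 24, 24), spacing = c(2, 2, 2),
                             lesion_center = c(23, 23, 23), lesion_radius_mm = 10,
                             lesion_suv = 5, seed = 1)
  vol_mm3 <- sum(ph$mask$data) * 8
  analytic <- 4 / 3 * pi * 10^3
  shell <- 4 * pi * 10^2 * 2  # one voxel-length shell
  expect_lt(abs(vol_mm3 - analytic), shell)
})

test_that("SUV metrics obey their definitional identities", {
  ph <- make_phantom(noise = 0.4, seed = 5)
  m <- suv_metrics(ph$volume, ph$mask)
  vals <- ph$volume$data[ph$mask$data]
  expect_equal(unname(m["SUVmin"]), min(vals))
  expect_equal(unname(m["SUVmax"]), max(vals))
  expect_equal(unname(m["SUVmean"]), mean(vals))
  expect_lte(m[["SUVpeak"]], m[["SUVmax"]])
  expect_gte(m[["SUVpeak"]], m[["SUVmin"]])
  expect_equal(m[["TL_PSMA"]], m[["SUVmean"]] * m[["PSMA_TV"]])
  expect_equal(m[["PSMA_TV"]], sum(ph$mask$data) * 0.008)
  # constant VOI: min = max = mean = peak
  phc <- make_phantom()
  mc <- suv_metrics(phc$volume, suv_metrics_mask <- phc$mask)
  expect_equal(unname(mc["SUVmean"]), 5)
  # brute-force SUVpeak oracle: best 1 ml sphere mean over in-mask centers
  d <- dim(ph$volume$data); sp <- ph$volume$spacing
  r <- (3 * 1000 / (4 * pi))^(1 / 3)
  centers <- which(ph$mask$data)
  peak_oracle <- max(vapply(centers, function(cix) {
    ci <- arrayInd(cix, d)
    acc <- c()
    for (i in 1:d[1]) for (j in 1:d[2]) for (k in 1:d[3]) {
      if (ph$mask$data[i, j, k] &&
          sqrt(sum(((c(i, j, k) - ci) * sp)^2)) <= r + 1e-9)
        acc <- c(acc, ph$volume$data[i, j, k])
    }
    mean(acc)
  }, numeric(1)))
  expect_equal(m[["SUVpeak"]], peak_oracle)
})

test_that("an 8-voxel VOI at 2 mm spacing gives PSMA-TV 0.064 ml", {
  vol <- suv_volume(array(5, dim = c(4, 4, 4)), c(2, 2, 2))
  msk <- array(FALSE, dim = c(4, 4, 4)); msk[1:2, 1:2, 1:2] <- TRUE
  m <- suv_metrics(vol, voi_mask(msk))
  expect_equal(m[["PSMA_TV"]], 0.064)
  expect_equal(m[["TL_PSMA"]], 0.32)
})

test_that("fixed-bin-width discretization references the in-mask minimum", {
  expect_equal(discretize_fixed_bin_width(c(0.0, 0.30, 0.61)), c(1L, 2L, 3L))
  expect_equal(discretize_fixed_bin_width(c(0.0, 0.30, 0.61) + 10), c(1L, 2L, 3L))
  expect_equal(discretize_fixed_bin_width(rep(2.2, 5)), rep(1L, 5))
  ph <- make_phantom(noise = 0.2, seed = 2)
  lab <- discretize_fixed_bin_width(ph$volume, ph$mask)
  expect_true(all(lab[!is.na(lab)] >= 1))
  expect_identical(is.na(lab), !ph$mask$data)
})

test_that("GLCM features match the exhaustive pair-enumeration oracle", {
  # two-level 4x4x1 checkerboard
  chk <- array(NA_integer_, dim = c(4, 4, 1))
  for (i in 1:4) for (j in 1:4) chk[i, j, 1] <- 1L + (i + j) %% 2L
  f <- glcm_features(chk)
  expect_equal(f[["joint_energy"]], oracle_glcm_energy(chk), tolerance = 1e-12)
  # random small phantoms
  withr::with_seed(31, {
    for (rep in 1:5) {
      a <- array(sample(1:4, 6^3, replace = TRUE), dim = c(6, 6, 6))
      a[sample(length(a), 60)] <- NA  # out-of-mask voxels
      f <- glcm_features(a)
      expect_equal(f[["joint_energy"]], oracle_glcm_energy(a), tolerance = 1e-12)
      expect_gt(f[["joint_energy"]], 0)
      expect_lte(f[["joint_energy"]], 1)
      expect_true(all(is.finite(f)))
    }
  })
})

test_that("constant VOI yields joint energy 1 and heterogeneity lowers it", {
  const <- array(1L, dim = c(4, 4, 2))
  expect_equal(glcm_features(const)[["joint_energy"]], 1.0)
  alt <- array(NA_integer_, dim = c(4, 4, 2))
  for (i in 1:4) for (j in 1:4) for (k in 1:2) alt[i, j, k] <- 1L + (i + j + k) %% 2L
  expect_lt(glcm_features(alt)[["joint_energy"]], 1.0)
  single <- array(NA_integer_, dim = c(3, 3, 1)); single[2, 2, 1] <- 1L
  expect_warning(f <- glcm_features(single), "fewer than 2")
  expect_true(all(is.na(f)))
})

test_that("first-order features follow their moment definitions", {
  expect_warning(f <- first_order_features(rep(3, 10)), "zero-variance")
  expect_equal(f[["skewness"]], 0)
  expect_equal(f[["kurtosis"]], 0)
  expect_equal(f[["entropy"]], 0)
  expect_equal(f[["maximum"]], 3)
  withr::with_seed(8, {
    for (rep in 1:20) {
      ph <- make_phantom(noise = 0.5, seed = rep)
      vals <- ph$volume$data[ph$mask$data]
      fo <- first_order_features(vals)
      m <- suv_metrics(ph$volume, ph$mask)
      expect_identical(fo[["maximum"]], m[["SUVmax"]])
    }
    z <- rnorm(1e4)
    fz <- first_order_features(z)
    expect_lt(abs(fz[["mean"]]), 3 / sqrt(1e4))
    expect_lt(abs(fz[["variance"]] - 1), 3 * sqrt(2 / 1e4))
  })
  expect_error(first_order_features(numeric(0)), "empty")
})

test_that("resampling preserves constants and linear ramps", {
  const <- suv_volume(array(4, dim = c(9, 9, 9)), c(1, 1, 1))
  msk <- voi_mask(array(TRUE, dim = c(9, 9, 9)))
  rs <- resample_isotropic(const, msk, target = 2)
  expect_equal(rs$volume$spacing, c(2, 2, 2))
  expect_true(all(abs(rs$volume$data - 4) < 1e-12))
  # already-2mm grid: identity at the knots
  v2 <- suv_volume(array(rnorm(5^3), dim = c(5, 5, 5)), c(2, 2, 2))
  rs2 <- resample_isotropic(v2, voi_mask(array(TRUE, dim = c(5, 5, 5))), 2)
  expect_equal(rs2$volume$data, v2$data, tolerance = 1e-12)
  # 1 mm -> 2 mm downsampling of a linear ramp preserves the ramp
  d <- c(11, 11, 11)
  ax <- (seq_len(11) - 1) * 1
  ramp <- array(0, dim = d)
  for (k in 1:11) ramp[, , k] <- outer(ax, ax, function(a, b) 0.5 * a + 0.2 * b) + 0.1 * ax[k]
  rsr <- resample_isotropic(suv_volume(ramp, c(1, 1, 1)),
                            voi_mask(array(TRUE, dim = d)), 2)
  axn <- (seq_len(dim(rsr$volume$data)[1]) - 1) * 2
  expected <- array(0, dim = dim(rsr$volume$data))
  for (k in seq_along(axn)) expected[, , k] <-
      outer(axn, axn, function(a, b) 0.5 * a + 0.2 * b) + 0.1 * axn[k]
  expect_equal(rsr$volume$data, expected, tolerance = 1e-6)
})

test_that("features ignore out-of-mask voxel values", {
  ph <- make_phantom(noise = 0.3, seed = 9)
  v2 <- ph$volume
  v2$data[!ph$mask$data] <- v2$data[!ph$mask$data] * 100 + 7
  a <- extract_radiomics(ph$volume, ph$mask, resample = FALSE)
  b <- extract_radiomics(v2, ph$mask, resample = FALSE)
  expect_equal(a, b)
})

test_that("extract_radiomics emits the tagged column contract and a hook", {
  ph <- make_phantom(noise = 0.2, seed = 3)
  f <- extract_radiomics(ph$volume, ph$mask,
                         extra_extractor = function(v, m)
                           c("rad::shape::voxel_count" = sum(m$data)))
  expect_true(all(grepl("^rad::(suv|firstorder|glcm|shape)::", names(f))))
  expect_true(all(is.finite(f)))
  expect_equal(f[["rad::firstorder::maximum"]], f[["rad::suv::SUVmax"]])
  expect_true("rad::shape::voxel_count" %in% names(f))
})
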