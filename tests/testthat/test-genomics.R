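test_that("CADD normalization is cohort-level min-max with degenerate rules", {
  expect_equal(normalize_cadd(c(10, 20, 30)), c(0, 0.5, 1))
  expect_equal(normalize_cadd(c(7, 7, 7)), c(0, 0, 0))
  expect_equal(normalize_cadd(5), 0)
  expect_equal(normalize_cadd(c(10, NA, 30)), c(0, NA, 1))
  expect_error(normalize_cadd(c(NA_real_, NA_real_)), "all CADD")
})

test_that("metascore is the mean of available normalized scores", {
  expect_equal(variant_metascore(1, 1, 1), 1)
  expect_equal(variant_metascore(NA, 0.4, 0.6), 0.5)
  expect_equal(variant_metascore(0.2, NA, NA), 0.2)
  expect_warning(m <- variant_metascore(c(0.5, NA), c(0.5, NA), c(0.5, NA)),
                 "no pathogenicity score")
  expect_equal(m, c(0.5, NA))
  expect_error(variant_metascore(0.5, 30, 0.5), "normalize CADD")
})

test_that("gene disruption sums metascores per gene", {
  v <- data.frame(gene = c("A", "A", "B"), metascore = c(0.2, 0.3, 0.7))
  d <- gene_disruption(v)
  expect_equal(d[["A"]], 0.5)
  expect_equal(d[["B"]], 0.7)
  expect_equal(gene_disruption(v, genes = c("A", "C"))[["C"]], 0)
  # unscorable variants are skipped
  v2 <- rbind(v, data.frame(gene = "A", metascore = NA))
  expect_equal(gene_disruption(v2)[["A"]], 0.5)
})

test_that("pathway disruption sums member genes, sharing genes across pathways", {
  gs <- c(gA = 0.5, gB = 1.0, gC = 0.25)
  cat <- list(p1 = c("gA", "gB"), p2 = c("gB", "gC", "gZ"), p3 = c("gX"))
  dp <- pathway_disruption(gs, cat)
  expect_equal(unname(dp), c(1.5, 1.25, 0))
  # conservation over disjoint pathways covering all mutated genes
  disj <- list(q1 = c("gA"), q2 = c("gB", "gC"))
  expect_equal(sum(pathway_disruption(gs, disj)), sum(gs))
})

test_that("TMB is variants per megabase", {
  expect_equal(compute_tmb(50, 25e6), 2)
  expect_equal(compute_tmb(0, 1e6), 0)
  expect_equal(compute_tmb(7, 3.5e6), 2)
  expect_error(compute_tmb(5, 0), "positive")
})

test_that("CNV burden is the covered fraction of the sequenced territory", {
  reg <- data.frame(start = 0, end = 100e6)
  expect_equal(compute_cnv_burden(data.frame(start = 0, end = 10e6), reg), 0.1)
  expect_equal(compute_cnv_burden(data.frame(start = numeric(0), end = numeric(0)), reg), 0)
  # overlapping segments merged before summation
  reg2 <- data.frame(start = 0, end = 100)
  seg <- data.frame(start = c(0, 5), end = c(10, 15))
  expect_equal(compute_cnv_burden(seg, reg2), 0.15)
  # segments outside the regions do not count; burden capped at 1
  seg2 <- data.frame(start = c(0, 200), end = c(100, 300))
  expect_equal(compute_cnv_burden(seg2, reg2), 1)
  expect_error(compute_cnv_burden(seg, reg2[0, ]), "non-empty")
})

test_that("CNV burden doubles with segment length until capped", {
  reg <- data.frame(start = 0, end = 1000)
  seg1 <- data.frame(start = c(0, 500), end = c(50, 550))
  seg2 <- data.frame(start = c(0, 500), end = c(100, 600))
  expect_equal(compute_cnv_burden(seg2, reg), 2 * compute_cnv_burden(seg1, reg))
})

test_that("mutated gene frequency supports the >=10% filter", {
  vt <- c(lapply(1:7, function(i) data.frame(gene = c("KMT2C", "SPOP"))),
          lapply(1:58, function(i) data.frame(gene = "SPOP")))
  names(vt) <- sprintf("P%02d", 1:65)
  freq <- mutated_gene_frequency(vt)
  expect_equal(freq$frequency[freq$gene == "KMT2C"], 7 / 65)
  expect_true(freq$frequency[freq$gene == "KMT2C"] >= 0.10)
  expect_equal(freq$frequency[freq$gene == "SPOP"], 1)
  expect_false("TP53" %in% freq$gene)
})

test_that("the full scoring chain matches brute-force oracles on random patients", {
  withr::with_seed(99, {
    for (rep in 1:50) {
      n_var <- sample(0:12, 1)
      genes <- sample(LETTERS[1:6], n_var, replace = TRUE)
      eve <- ifelse(runif(n_var) < 0.3, NA, runif(n_var))
      cadd <- ifelse(runif(n_var) < 0.3, NA, rgamma(n_var, 3, 1 / 8))
      poly <- ifelse(runif(n_var) < 0.3, NA, runif(n_var))
      v <- data.frame(gene = genes, eve = eve, cadd = cadd, polyphen = poly)
      cn <- if (all(is.na(cadd))) rep(NA_real_, n_var) else {
        rng <- range(cadd, na.rm = TRUE)
        if (n_var == 0) numeric(0)
        else if (diff(rng) == 0) ifelse(is.na(cadd), NA, 0)
        else (cadd - rng[1]) / diff(rng)
      }
      m <- suppressWarnings(variant_metascore(eve, cn, poly))
      # oracle: elementwise mean of available scores
      oracle_m <- vapply(seq_len(max(n_var, 0)), function(i) {
        s <- c(eve[i], cn[i], poly[i]); s <- s[!is.na(s)]
        if (length(s)) mean(s) else NA_real_
      }, numeric(1))
      expect_equal(m, oracle_m, tolerance = 1e-12)
      d <- gene_disruption(data.frame(gene = genes, metascore = m),
                           genes = LETTERS[1:6])
      oracle_d <- vapply(LETTERS[1:6], function(g)
        sum(oracle_m[genes == g], na.rm = TRUE), numeric(1))
      expect_equal(d, oracle_d, tolerance = 1e-12)
      cat6 <- list(pw1 = LETTERS[1:3], pw2 = LETTERS[3:6])
      expect_equal(unname(pathway_disruption(d, cat6)),
                   c(sum(oracle_d[1:3]), sum(oracle_d[3:6])), tolerance = 1e-12)
      # TMB oracle
      size <- sample(c(1e6, 3.5e6, 3e7), 1)
      expect_equal(compute_tmb(n_var, size), n_var * 1e6 / size, tolerance = 1e-12)
      # CNV union oracle on an integer grid
      k <- sample(0:5, 1)
      seg <- data.frame(start = sample(0:900, k), end = rep(0, k))
      seg$end <- seg$start + sample(10:200, k, replace = TRUE)
      reg <- data.frame(start = c(0, 500), end = c(400, 1000))
      covered_grid <- logical(1000)
      for (i in seq_len(k)) covered_grid[(seg$start[i] + 1):min(seg$end[i], 1000)] <- TRUE
      region_grid <- logical(1000)
      region_grid[c(1:400, 501:1000)] <- TRUE
      expect_equal(compute_cnv_burden(seg, reg),
                   sum(covered_grid & region_grid) / sum(region_grid),
                   tolerance = 1e-12)
    }
  })
})

test_that("disruption is monotone: adding a positive-score variant never decreases", {
  v <- data.frame(gene = c("A", "B"), metascore = c(0.4, 0.2))
  cat <- list(p = c("A", "B"))
  d0 <- pathway_disruption(gene_disruption(v, c("A", "B")), cat)
  v2 <- rbind(v, data.frame(gene = "A", metascore = 0.3))
  d1 <- pathway_disruption(gene_disruption(v2, c("A", "B")), cat)
  expect_true(all(d1 >= d0))
  expect_gt(compute_tmb(3, 1e6), compute_tmb(2, 1e6))
})

test_that("genomics block has one column per pathway plus TMB and CNV burden", {
  co <- default_cohort()
  blk <- genomics_block(co$variant_tables, co$cnv_tables,
                        co$sequenced_regions, co$gene_sets)
  expect_equal(ncol(blk) - 1L, length(co$gene_sets) + 2L)  # 51 + 2 = 53
  m <- as.matrix(blk[, -1])
  expect_true(all(m >= 0))
  expect_true(all(blk$CNV_burden <= 1))
})
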