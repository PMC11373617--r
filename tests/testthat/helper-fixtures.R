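# Shared fixtures and independent oracles for the test suite.
# Cohorts used by several test files are built once per run and memoized.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_env)) assign(name, builder(), envir = .fixture_env)
  get(name, envir = .fixture_env)
}

default_cohort <- function() {
  fixture("default_cohort", function() generate_cohort(cohort_config(seed = 101)))
}

default_table <- function() {
  fixture("default_table", function() cohort_design_matrix(default_cohort()))
}

# A reduced-schema cohort with planted effects, for pipeline plumbing tests.
small_table <- function() {
  fixture("small_table", function() {
    co <- generate_cohort(cohort_config(
      n_patients = 40, n_pathways = 8, n_genes = 60, n_radiomics = 20,
      n_markers = 3, seed = 71,
      effect_map = c("rad::suv::SUVmean" = 2, "clin::psa_preop" = 2)))
    cohort_design_matrix(co)
  })
}

small_config <- function(algo = "rf", folds = 6) {
  pipeline_config(algorithm = algo, n_folds = folds, search_budget = 4L,
                  mrmr_k_grid = c(3L, 5L), seed = 42)
}

# A tiny labeled feature table with known structure, for pipeline plumbing.
toy_table <- function(n = 40, p = 12, effect = 2, seed = 7) {
  withr::with_seed(seed, {
    y <- factor(rep(c("low", "high"), length.out = n), levels = c("low", "high"))
    x <- matrix(rnorm(n * p), n, p, dimnames = list(sprintf("P%02d", 1:n),
                                                    sprintf("f%02d", 1:p)))
    x[, 1] <- x[, 1] + ifelse(y == "high", effect / 2, -effect / 2)
    list(x = x, y = y)
  })
}

# Independent brute-force GLCM oracle: enumerate every in-mask voxel pair for
# every direction, count co-occurrences, symmetrize, normalize.
oracle_glcm <- function(labels, directions, distance = 1) {
  d <- dim(labels)
  nlev <- max(labels, na.rm = TRUE)
  mats <- list()
  for (k in seq_len(nrow(directions))) {
    off <- directions[k, ] * distance
    cnt <- matrix(0, nlev, nlev)
    for (i in 1:d[1]) for (j in 1:d[2]) for (l in 1:d[3]) {
      if (is.na(labels[i, j, l])) next
      ii <- i + off[1]; jj <- j + off[2]; ll <- l + off[3]
      if (ii < 1 || ii > d[1] || jj < 1 || jj > d[2] || ll < 1 || ll > d[3]) next
      if (is.na(labels[ii, jj, ll])) next
      a <- labels[i, j, l]; b <- labels[ii, jj, ll]
      cnt[a, b] <- cnt[a, b] + 1
      cnt[b, a] <- cnt[b, a] + 1
    }
    if (sum(cnt) > 0) mats[[length(mats) + 1]] <- cnt / sum(cnt)
  }
  mats
}

oracle_glcm_energy <- function(labels, distance = 1) {
  dirs <- gleasonomics:::.glcm_directions()
  mats <- oracle_glcm(labels, dirs, distance)
  mean(vapply(mats, function(p) sum(p^2), numeric(1)))
}

# Exhaustive greedy mRMR oracle with its own entropy-based MI estimator.
oracle_mi <- function(a, b) {
  ent <- function(v) {
    p <- table(v) / length(v)
    -sum(p * log(p))
  }
  ent(a) + ent(b) - ent(paste(a, b))
}

oracle_mrmr <- function(x, y, k) {
  n <- nrow(x)
  nb <- max(min(5, floor(n / 5)), 2)
  disc <- apply(x, 2, function(col) {
    ux <- sort(unique(col))
    if (length(ux) <= nb) return(match(col, ux))
    qs <- unique(quantile(col, probs = seq(0, 1, length.out = nb + 1), type = 7,
                          names = FALSE))
    if (length(qs) < 2) rep(1L, length(col)) else
      as.integer(cut(col, breaks = qs, include.lowest = TRUE))
  })
  yc <- as.integer(as.factor(y))
  sel <- integer(0)
  for (step in seq_len(k)) {
    cand <- setdiff(seq_len(ncol(x)), sel)
    crit <- sapply(cand, function(j) {
      rel <- oracle_mi(disc[, j], yc)
      red <- if (length(sel)) mean(sapply(sel, function(s) oracle_mi(disc[, j], disc[, s]))) else 0
      rel - red
    })
    sel <- c(sel, cand[which.max(crit)])
  }
  colnames(x)[sel]
}

# Direct-formula chi-square oracle for an r x c contingency table.
oracle_chisq <- function(tab) {
  e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  stat <- sum((tab - e)^2 / e)
  df <- (nrow(tab) - 1) * (ncol(tab) - 1)
  list(statistic = stat, p_value = pchisq(stat, df, lower.tail = FALSE))
}
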