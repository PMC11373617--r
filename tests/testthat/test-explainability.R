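trained_pair <- function() {
  fixture("trained_pair", function() {
    d <- toy_table(n = 80, p = 6, effect = 3, seed = 19)
    model <- fit_model("lgr", d$x[, c("f01", "f02")], d$y,
                       list(alpha = 0, lambda = 1e-3), seed = 1)
    list(d = d, model = model)
  })
}

test_that("permutation importance is zero for unused features, seeded, positive for signal", {
  tp <- trained_pair()
  imp <- permutation_importance(tp$model, tp$d$x, tp$d$y, seed = 3)
  # f03..f06 are not in the model: exactly zero
  expect_true(all(imp$importance[imp$feature %in% paste0("f0", 3:6)] == 0))
  expect_gt(imp$importance[imp$feature == "f01"], 0.2)
  imp2 <- permutation_importance(tp$model, tp$d$x, tp$d$y, seed = 3)
  expect_identical(imp, imp2)
  # monotone relabeling of an unused feature changes nothing
  x2 <- tp$d$x; x2[, "f05"] <- exp(x2[, "f05"])
  imp3 <- permutation_importance(tp$model, x2, tp$d$y, seed = 3)
  expect_identical(imp3$importance, imp$importance)
})

test_that("the sole informative feature of a near-perfect model carries ~ AUC - 0.5", {
  withr::with_seed(40, {
    y <- factor(rep(c("low", "high"), each = 100), levels = c("low", "high"))
    x <- cbind(sig = ifelse(y == "high", 2, -2) + rnorm(200, sd = 0.05),
               nul = rnorm(200))
    m <- fit_model("lgr", x, y, list(alpha = 0, lambda = 1e-4), seed = 2)
    base <- gleasonomics:::.auc_midrank(predict_scores(m, x), y)
    imp <- permutation_importance(m, x, y, n_repeats = 20, seed = 5)
    got <- imp$importance[imp$feature == "sig"]
    expect_lt(abs(got - (base - 0.5)), 0.05)
  })
})

test_that("category importance averages per tag and keeps singletons", {
  imp <- data.frame(feature = c("a", "b", "c"), importance = c(0.4, 0.2, 0.1))
  cats <- c(a = "radiomics", b = "radiomics", c = "bxISUP")
  ci <- category_importance(imp, cats)
  expect_equal(ci$mean_importance[ci$category == "radiomics"], 0.3)
  expect_equal(ci$mean_importance[ci$category == "bxISUP"], 0.1)
  zero <- category_importance(data.frame(feature = c("a", "b", "c"),
                                         importance = 0), cats)
  expect_true(all(zero$mean_importance == 0))
  expect_error(category_importance(imp, cats[1:2]), "untagged")
})

test_that("Shapley values of an additive model recover the coordinates", {
  withr::with_seed(9, {
    bg <- matrix(rnorm(400), 200, 2, dimnames = list(NULL, c("x1", "x2")))
    bg <- scale(bg, scale = FALSE)  # centered background
    f <- function(m) m[, "x1"] + m[, "x2"]
    pat <- c(x1 = 1.3, x2 = -0.4)
    phi <- shapley_estimate(f, bg, pat, n_coalitions = 400, seed = 6)
    # closed form for additive models: phi_j = x_j - E[background_j]
    expect_lt(abs(phi[["x1"]] - 1.3), 0.15)
    expect_lt(abs(phi[["x2"]] + 0.4), 0.15)
    # telescoping additivity: sum of values = f(x) - estimated baseline
    expect_equal(sum(phi),
                 unname(f(matrix(pat, 1, dimnames = list(NULL, names(pat)))) -
                          attr(phi, "baseline")), tolerance = 1e-12)
  })
})

test_that("duplicated features share credit and null features vanish", {
  withr::with_seed(26, {
    bg <- matrix(rnorm(300), 100, 3,
                 dimnames = list(NULL, c("a", "b", "nul")))
    bg[, "b"] <- bg[, "a"]
    f <- function(m) m[, "a"] + m[, "b"]
    diffs <- vapply(1:10, function(r)
      abs(diff(shapley_estimate(f, bg, c(a = 1, b = 1, nul = 5),
                                n_coalitions = 150, seed = r)[c("a", "b")])),
      numeric(1))
    expect_lt(mean(diffs), 0.2)  # symmetric in expectation
    phi_small <- shapley_estimate(f, bg, c(a = 1, b = 1, nul = 5),
                                  n_coalitions = 50, seed = 1)
    phi_big <- shapley_estimate(f, bg, c(a = 1, b = 1, nul = 5),
                                n_coalitions = 800, seed = 1)
    expect_lte(abs(phi_big[["nul"]]), abs(phi_small[["nul"]]) + 1e-9)
    expect_lt(abs(phi_big[["nul"]]), 0.05)
  })
  bg3 <- matrix(0, 5, 3, dimnames = list(NULL, c("a", "b", "c")))
  expect_error(shapley_estimate(function(m) m[, 1], bg3, c(a = 0, b = 0, c = 0),
                                n_coalitions = 2), "at least")
})

test_that("a depth-2 tree reference is reproduced with fidelity 1", {
  withr::with_seed(3, {
    x <- matrix(runif(300 * 3), 300, 3, dimnames = list(NULL, c("u", "v", "w")))
    ref <- function(m) ifelse(m[, "u"] > 0.5,
                              ifelse(m[, "v"] > 0.3, 0.9, 0.6), 0.1)
    sur <- fit_surrogate(ref, x, max_depth = 2, seed = 4)
    expect_equal(sur$fidelity_auc, 1.0)
    expect_true(all(sur$features_used %in% c("u", "v")))
    expect_lte(sur$max_depth, 2)
    expect_true(length(sur$rules) >= 2)
  })
})

test_that("surrogate fidelity is monotone in depth and finds planted splits", {
  tp <- trained_pair()
  ref <- function(m) predict_scores(tp$model, m)
  fids <- vapply(1:3, function(d)
    fit_surrogate(ref, tp$d$x, max_depth = d, seed = 11)$fidelity_insample,
    numeric(1))
  expect_true(all(diff(fids) >= -1e-9))
  hits <- vapply(1:10, function(r) {
    sur <- fit_surrogate(ref, tp$d$x, max_depth = 2, seed = r)
    all(sur$features_used %in% c("f01", "f02"))
  }, logical(1))
  expect_gte(mean(hits), 0.9)
  expect_error(fit_surrogate(function(m) rep(0.7, nrow(m)), tp$d$x),
               "constant")
})

test_that("importance over folds aggregates models and flags selection", {
  tab <- small_table()
  res <- run_experiment(tab, small_config(folds = 4))
  iof <- importance_over_folds(res, n_repeats = 4, seed = 2)
  expect_true(all(c("feature", "importance", "n_folds_selected") %in% names(iof)))
  sel_any <- iof$n_folds_selected > 0
  expect_true(all(iof$importance[!sel_any] == 0))
  # the planted features dominate the ranking
  expect_true(any(iof$feature[1:4] %in% c("rad::suv::SUVmean", "clin::psa_preop")))
})
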