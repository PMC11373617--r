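# Descriptive statistics layer: group comparisons and the experiment report.

#' Compare a variable between the two risk groups
#'
#' Quantitative variables are compared with the two-sided Mann-Whitney
#' (Wilcoxon rank-sum) test; categorical variables with the chi-square test
#' on a contingency table (no continuity correction by default; rows with
#' missing category excluded unless `na_as_level`).
#'
#' @param values numeric vector (quantitative) or vector/factor of categories
#'   (categorical). Alternatively, for categorical input, a precomputed
#'   contingency matrix (categories x groups) with `groups = NULL`.
#' @param groups factor/vector of group membership aligned with `values`.
#' @param type `"quantitative"` or `"categorical"`.
#' @param correct continuity correction for the chi-square test (default
#'   `FALSE`).
#' @param na_as_level treat missing category as its own level (default
#'   `FALSE`: NA rows are excluded).
#' @return object of class `group_comparison`: list with `variable_type`,
#'   `test`, `statistic`, `p_value`, `significant` (at 0.05), `summary`
#'   (per-group mean/SD or counts).
#' @export
compare_groups <- function(values, groups = NULL, type = c("quantitative", "categorical"),
                           correct = FALSE, na_as_level = FALSE) {
  type <- match.arg(type)
  if (type == "quantitative") {
    stopifnot(!is.null(groups))
    g <- as.factor(groups)
    if (nlevels(droplevels(g[!is.na(values)])) != 2L) stop("need two non-empty groups")
    ht <- suppressWarnings(stats::wilcox.test(values ~ g, exact = FALSE,
                                              correct = FALSE))
    smry <- do.call(rbind, lapply(split(values, g), function(v)
      data.frame(mean = mean(v, na.rm = TRUE), sd = stats::sd(v, na.rm = TRUE))))
    test_name <- "rank-sum"
  } else {
    if (is.matrix(values)) {
      tab <- values
    } else {
      v <- values
      if (na_as_level) v <- addNA(as.factor(v), ifany = TRUE)
      keep <- na_as_level | !is.na(v)
      tab <- table(v[keep], as.factor(groups)[keep])
    }
    if (any(dim(tab) < 2L) || any(colSums(tab) == 0)) stop("need two non-empty groups")
    ht <- suppressWarnings(stats::chisq.test(tab, correct = correct))
    smry <- as.data.frame.matrix(tab)
    test_name <- "chi-square"
  }
  structure(list(variable_type = type, test = test_name,
                 statistic = unname(ht$statistic), p_value = ht$p.value,
                 significant = ht$p.value < 0.05, summary = smry),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat("<group_comparison> ", x$test, ": statistic ",
      sprintf("%.4g", x$statistic), ", p ",
      format.pval(x$p_value, digits = 3), if (x$significant) " *" else "",
      "\n", sep = "")
  invisible(x)
}

#' Build the end-to-end experiment report
#'
#' Collects the cross-validation summary, importance analyses, surrogate
#' workflow and cohort comparisons into one machine-readable bundle, and
#' optionally runs the feature-type ablation (each configured combination of
#' omics blocks re-run through the pipeline).
#'
#' @param cv a `cv_summary` from [run_experiment()].
#' @param importance per-feature importance data.frame (may be `NULL`).
#' @param category_importance per-category importance data.frame (may be
#'   `NULL`).
#' @param surrogate a `surrogate_tree` (may be `NULL`).
#' @param comparisons named list of `group_comparison` objects (may be
#'   empty).
#' @param ablation named list of `cv_summary` objects keyed by feature-type
#'   combination (may be `NULL`); rendered as a combination x metric table.
#' @return object of class `omics_report` (a list); serialize with
#'   [write_report()].
#' @export
build_report <- function(cv, importance = NULL, category_importance = NULL,
                         surrogate = NULL, comparisons = list(), ablation = NULL) {
  stopifnot(inherits(cv, "cv_summary"))
  perf <- cv$summary
  abl_tab <- NULL
  if (!is.null(ablation)) {
    abl_tab <- do.call(rbind, lapply(names(ablation), function(nm) {
      s <- ablation[[nm]]$summary
      row <- as.data.frame(as.list(stats::setNames(s$mean, s$metric)))
      cbind(feature_types = nm, row)
    }))
  }
  comp_tab <- if (length(comparisons)) {
    data.frame(variable = names(comparisons),
               test = vapply(comparisons, `[[`, character(1), "test"),
               statistic = vapply(comparisons, `[[`, numeric(1), "statistic"),
               p_value = vapply(comparisons, `[[`, numeric(1), "p_value"),
               row.names = NULL)
  } else NULL
  structure(list(performance = perf,
                 selection_frequency = cv$selection_frequency,
                 importance = importance,
                 category_importance = category_importance,
                 surrogate_rules = if (!is.null(surrogate)) surrogate$rules,
                 surrogate_fidelity = if (!is.null(surrogate)) surrogate$fidelity_auc,
                 ablation = abl_tab,
                 cohort_comparisons = comp_tab),
            class = "omics_report")
}

#' Serialize a report bundle
#'
#' Writes the report as pretty-printed JSON plus CSV tables and, when a
#' surrogate is present, a plain-text decision flowchart.
#'
#' @param report an `omics_report`.
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "omics_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, "report.json")
  ser <- report
  class(ser) <- NULL
  ser$selection_frequency <- as.list(ser$selection_frequency)
  jsonlite::write_json(ser, paths[1], auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  utils::write.csv(report$performance, file.path(dir, "performance.csv"),
                   row.names = FALSE)
  paths <- c(paths, file.path(dir, "performance.csv"))
  if (!is.null(report$ablation)) {
    utils::write.csv(report$ablation, file.path(dir, "ablation.csv"),
                     row.names = FALSE)
    paths <- c(paths, file.path(dir, "ablation.csv"))
  }
  if (!is.null(report$surrogate_rules)) {
    p <- file.path(dir, "surrogate_workflow.txt")
    writeLines(c("Simplified diagnostic workflow (surrogate decision tree)",
                 sprintf("Fidelity AUC vs reference model: %.3f",
                         report$surrogate_fidelity),
                 "", report$surrogate_rules), p)
    paths <- c(paths, p)
  }
  invisible(paths)
}
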