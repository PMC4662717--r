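# End-to-end runs: formula-composition analysis (PCA -> discriminating
# axes -> Deficiency/Excess PLS with Q^2 component selection ->
# coefficient table) and metabolome-fingerprint analysis (PCA on the
# leading axes -> PLS on non-Middle samples -> optional exclusion
# re-run). Every filtering step is reported with counts, since the
# N/M bookkeeping (dropped Middle rows, dropped all-zero drug columns,
# out-of-range peaks) is part of the analysis record.

run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    abort(sprintf("[stage %s] %s", stage, conditionMessage(e)))
  })
}

#' Run the formula-composition analysis
#'
#' Load/validate -> PCA on all formulas -> t-test selection of the two
#' most Deficiency/Excess-discriminating axes -> restrict to Deficiency
#' and Excess rows (dropping drug columns that become all-zero) -> PLS1
#' with cross-validated Q-squared component selection -> sign
#' classification, recognition rate and coefficient table.
#'
#' @param input A composition tibble or a path readable by
#'   [read_formula_table()].
#' @param pca_center,pca_scale PCA preprocessing flags.
#' @param variance_threshold Candidate-axis variance filter (default 0.01).
#' @param ttest `"welch"` or `"pooled"`.
#' @param cv,kfold_k,a_max,pls_scale Passed to [select_ncomp()].
#' @param coef_threshold |b| filter for the coefficient table.
#' @param out_dir Optional directory; when given, the report and
#'   intermediates (scores, coefficients, predictions, model) are written.
#' @return A `sho_report` list with all headline quantities and the
#'   fitted objects.
#' @export
run_formula_analysis <- function(input,
                                 pca_center = TRUE, pca_scale = FALSE,
                                 variance_threshold = 0.01,
                                 ttest = "welch",
                                 cv = "loo", kfold_k = 7, a_max = NULL,
                                 pls_scale = FALSE, coef_threshold = 0.1,
                                 out_dir = NULL) {
  data <- run_stage("load", {
    if (is.character(input)) read_formula_table(input) else as_formula_tbl(input)
  })
  class_counts <- table(data$sho)

  pca <- run_stage("pca", fit_pca(data, center = pca_center, scale = pca_scale))
  sel <- run_stage("axis_selection",
                   select_discriminating_axes(pca,
                                              variance_threshold = variance_threshold,
                                              ttest = ttest))
  de <- run_stage("subset", subset_by_sho(data, c("Deficiency", "Excess")))
  cvres <- run_stage("component_selection",
                     select_ncomp(de, a_max = a_max, cv = cv,
                                  kfold_k = kfold_k, scale = pls_scale))
  fit <- run_stage("pls_fit", fit_pls1(de, ncomp = cvres$ncomp, scale = pls_scale))
  pred <- run_stage("prediction",
                    predict(fit, labels = ifelse(fit$y > 0, "Excess", "Deficiency")))
  coefs <- run_stage("coefficients", coefficient_table(fit, threshold = coef_threshold))

  report <- structure(list(
    kind = "formulas",
    n = nrow(data),
    n_drugs = length(setdiff(names(data), c("formula_id", "sho"))),
    class_counts = as.list(class_counts),
    n_pls = length(fit$y),
    n_drugs_pls = length(fit$b),
    dropped_drugs = attr(de, "dropped_drugs"),
    pca_proportions = pca$proportions,
    candidate_axes = sel$candidates,
    chosen_axes = sel$chosen_axes,
    total_candidate_variance = sel$total_candidate_variance,
    ncomp = cvres$ncomp,
    q2 = cvres$q2,
    q2_curve = cvres$curve,
    recognition_rate = recognition_rate(pred),
    misclassified = attr(pred, "misclassified"),
    coefficients = coefs,
    pca = pca, selection = sel, cv = cvres, fit = fit, prediction = pred
  ), class = "sho_report")
  if (!is.null(out_dir)) write_run_report(report, out_dir)
  report
}

#' Run the metabolome-fingerprint analysis
#'
#' PCA of the binned intensity matrix (proportions are reported for both
#' centered-only and autoscaled preprocessing; the score plot and
#' downstream steps use the requested setting) -> PLS1 on the non-Middle
#' samples with cross-validated component selection -> sign
#' classification -> optional exclusion re-run (component count
#' re-selected on the reduced set).
#'
#' @param input Fingerprint tibble or a path readable by
#'   [read_binned_matrix()].
#' @param labels Optional label sidecar (tibble or CSV path,
#'   `sample_id, sho`), required when `input` carries no `sho` column.
#' @param exclude Character sample ids for the sensitivity re-run
#'   (default none).
#' @param pca_scale Use autoscaled preprocessing for the main PCA
#'   (default `FALSE`: centered only).
#' @param cv,kfold_k,a_max,pls_scale Passed to [select_ncomp()].
#' @param out_dir Optional output directory.
#' @return A `sho_report` list.
#' @export
run_metabolome_analysis <- function(input, labels = NULL,
                                    exclude = character(0),
                                    pca_scale = FALSE,
                                    cv = "loo", kfold_k = 7, a_max = NULL,
                                    pls_scale = FALSE, out_dir = NULL) {
  data <- run_stage("load", {
    if (is.character(input)) {
      read_binned_matrix(input, labels = labels)
    } else {
      fp <- tibble::as_tibble(input)
      if (!is.null(labels) && !"sho" %in% names(fp)) {
        if (is.character(labels)) {
          labels <- readr::read_csv(labels, show_col_types = FALSE, progress = FALSE)
        }
        fp <- attach_labels(fp, labels, attr(input, "grid"))
      }
      fp
    }
  })
  if (!"sho" %in% names(data)) abort("[stage load] No Sho labels supplied.")
  class_counts <- table(parse_sho(data$sho))

  pca <- run_stage("pca", fit_pca(data, center = TRUE, scale = pca_scale))
  prop_centered <- if (pca_scale) fit_pca(data, center = TRUE, scale = FALSE)$proportions else pca$proportions
  prop_scaled <- if (pca_scale) pca$proportions else {
    # constant bins make autoscaling undefined; report NULL in that case
    tryCatch(fit_pca(data, center = TRUE, scale = TRUE)$proportions,
             error = function(e) NULL)
  }

  non_middle <- data[parse_sho(data$sho) != "Middle", , drop = FALSE]
  cvres <- run_stage("component_selection",
                     select_ncomp(non_middle, a_max = a_max, cv = cv,
                                  kfold_k = kfold_k, scale = pls_scale))
  fit <- run_stage("pls_fit",
                   fit_pls1(non_middle, ncomp = cvres$ncomp, scale = pls_scale))
  pred <- run_stage("prediction",
                    predict(fit, labels = ifelse(fit$y > 0, "Excess", "Deficiency")))

  exclusion_run <- NULL
  if (length(exclude) > 0) {
    exclusion_run <- run_stage("exclusion_rerun",
                               refit_excluding(non_middle, exclude,
                                               a_max = a_max, cv = cv,
                                               kfold_k = kfold_k,
                                               scale = pls_scale))
  }

  report <- structure(list(
    kind = "metabolome",
    n = nrow(data),
    n_bins = length(setdiff(names(data), c("sample_id", "sho"))),
    class_counts = as.list(class_counts),
    n_pls = length(fit$y),
    pca_proportions = pca$proportions,
    proportions_centered = prop_centered,
    proportions_autoscaled = prop_scaled,
    pca_preprocessing = if (pca_scale) "autoscaled" else "centered",
    ncomp = cvres$ncomp,
    q2 = cvres$q2,
    q2_curve = cvres$curve,
    recognition_rate = recognition_rate(pred),
    misclassified = attr(pred, "misclassified"),
    excluded = exclude,
    recognition_rate_excluded = if (!is.null(exclusion_run))
      recognition_rate(exclusion_run$prediction) else NULL,
    pca = pca, cv = cvres, fit = fit, prediction = pred,
    exclusion_run = exclusion_run
  ), class = "sho_report")
  if (!is.null(out_dir)) write_run_report(report, out_dir)
  report
}

#' @export
print.sho_report <- function(x, ...) {
  cat(format_report_text(x), sep = "\n")
  invisible(x)
}

format_report_text <- function(x) {
  lines <- c(
    sprintf("== %s analysis ==", x$kind),
    sprintf("Samples: %d (%s)", x$n,
            paste(sprintf("%s %d", names(x$class_counts),
                          unlist(x$class_counts)), collapse = ", "))
  )
  if (x$kind == "formulas") {
    lines <- c(lines,
      sprintf("Drugs: %d overall, %d entering PLS (%d all-zero column(s) dropped)",
              x$n_drugs, x$n_drugs_pls, length(x$dropped_drugs)),
      sprintf("PCA: %d candidate axes > %s variance, %s total; chosen PC %d and PC %d",
              nrow(x$candidate_axes),
              format_pct(100 * x$selection$variance_threshold),
              format_pct(100 * x$total_candidate_variance),
              x$chosen_axes[1], x$chosen_axes[2]),
      sprintf("  smallest p-values: PC %d (p = %.2g), PC %d (p = %.2g)",
              x$chosen_axes[1],
              x$candidate_axes$p_value[match(x$chosen_axes[1], x$candidate_axes$component)],
              x$chosen_axes[2],
              x$candidate_axes$p_value[match(x$chosen_axes[2], x$candidate_axes$component)])
    )
  } else {
    p <- x$pca_proportions
    lines <- c(lines,
      sprintf("Bins: %d; PCA preprocessing: %s", x$n_bins, x$pca_preprocessing),
      sprintf("PCA: PC1 %s, PC1-2 %s, PC1-5 %s of variance",
              format_pct(100 * p[1]),
              format_pct(100 * sum(p[1:min(2, length(p))])),
              format_pct(100 * sum(p[1:min(5, length(p))]))),
      sprintf("PLS samples (non-Middle): %d", x$n_pls)
    )
  }
  lines <- c(lines,
    sprintf("PLS: A = %d selected by cross-validated Q2 = %.3f", x$ncomp, x$q2),
    sprintf("Recognition rate: %s (%d/%d; misclassified: %s)",
            format_pct(100 * x$recognition_rate),
            round(x$recognition_rate * x$n_pls), x$n_pls,
            if (length(x$misclassified) > 0)
              paste(x$misclassified, collapse = ", ") else "none")
  )
  if (!is.null(x$recognition_rate_excluded)) {
    lines <- c(lines, sprintf(
      "After excluding %s: recognition rate %s on %d samples",
      paste(x$excluded, collapse = ", "),
      format_pct(100 * x$recognition_rate_excluded),
      x$n_pls - length(x$excluded)))
  }
  if (!is.null(x$coefficients)) {
    lines <- c(lines, sprintf("%d drugs pass |b| > 0.1", nrow(x$coefficients)))
  }
  lines
}

# Numeric-only view of a report, used for JSON serialization and for
# determinism checks (identical config + seed => identical numbers).
report_numbers <- function(x) {
  out <- list(
    kind = x$kind,
    n = x$n,
    class_counts = x$class_counts,
    n_pls = x$n_pls,
    pca_proportions = unname(x$pca_proportions),
    ncomp = x$ncomp,
    q2 = x$q2,
    q2_curve = as.list(x$q2_curve),
    recognition_rate = x$recognition_rate,
    misclassified = as.character(x$misclassified)
  )
  if (x$kind == "formulas") {
    out$n_drugs <- x$n_drugs
    out$n_drugs_pls <- x$n_drugs_pls
    out$chosen_axes <- x$chosen_axes
    out$candidate_axes <- as.list(x$candidate_axes)
    out$total_candidate_variance <- x$total_candidate_variance
    out$coefficients <- as.list(x$coefficients)
  } else {
    out$n_bins <- x$n_bins
    out$pca_preprocessing <- x$pca_preprocessing
    out$proportions_centered <- unname(x$proportions_centered)
    if (!is.null(x$proportions_autoscaled)) {
      out$proportions_autoscaled <- unname(x$proportions_autoscaled)
    }
    if (!is.null(x$recognition_rate_excluded)) {
      out$excluded <- x$excluded
      out$recognition_rate_excluded <- x$recognition_rate_excluded
    }
  }
  out
}

#' Write a run report and its intermediates
#'
#' Writes `report.txt` (fixed-precision display: rates to 0.1 %),
#' `report.json` (full precision), `scores_pca.csv`, `predictions.csv`,
#' `model.json`, and for formula runs `coefficients.csv`.
#'
#' @param report A `sho_report`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_run_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  writeLines(format_report_text(report), file.path(dir, "report.txt"))
  jsonlite::write_json(report_numbers(report), file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  axes <- if (report$kind == "formulas") report$chosen_axes else c(1, 2)
  readr::write_csv(project_scores(report$pca, axes),
                   file.path(dir, "scores_pca.csv"), progress = FALSE)
  readr::write_csv(tibble::as_tibble(report$prediction),
                   file.path(dir, "predictions.csv"), progress = FALSE)
  if (!is.null(report$coefficients)) {
    readr::write_csv(report$coefficients, file.path(dir, "coefficients.csv"),
                     progress = FALSE)
  }
  fit <- report$fit
  model <- list(
    ncomp = fit$A, scale = fit$scale,
    x_mean = as.list(setNames(fit$x_mean, fit$variables)),
    y_mean = fit$y_mean,
    coefficients = as.list(setNames(fit$b, fit$variables)),
    intercept = fit$b0,
    y_loadings = fit$q,
    q2_curve = as.list(report$q2_curve)
  )
  jsonlite::write_json(model, file.path(dir, "model.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Read a pipeline configuration from YAML
#'
#' Keys mirror the function arguments, grouped as `pca:` (`center`,
#' `scale`, `variance_threshold`, `ttest`) and `pls:` (`cv`, `kfold_k`,
#' `a_max`, `scale`, `coef_threshold`), plus top-level `input`, `labels`,
#' `exclude`, `out_dir`, `seed`.
#'
#' @param path YAML file path.
#' @return A named list of configuration values.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  defaults <- list(
    pca = list(center = TRUE, scale = FALSE, variance_threshold = 0.01,
               ttest = "welch"),
    pls = list(cv = "loo", kfold_k = 7, a_max = NULL, scale = FALSE,
               coef_threshold = 0.1)
  )
  cfg$pca <- utils::modifyList(defaults$pca, cfg$pca %||% list())
  cfg$pls <- utils::modifyList(defaults$pls, cfg$pls %||% list())
  cfg
}
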