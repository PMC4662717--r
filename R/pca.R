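# PCA with the diagnostics used for Sho classification: variance
# proportions Pr(Z_k), factor loadings r(Z_k, X_j) as score-variable
# correlations, and selection of class-discriminating axes by two-sample
# t-test on the scores of Deficiency vs Excess rows.

#' Principal component analysis of a composition or fingerprint table
#'
#' Computed by singular value decomposition (via [stats::prcomp()]).
#' Loading vectors have unit Euclidean norm; scores are the projections of
#' the (centered, optionally scaled) data onto them; the proportion of
#' component k is Var(Z_k) divided by the total variance. The sign of each
#' component is fixed by making its largest-magnitude loading entry
#' positive, so results are fully deterministic.
#'
#' @param df Composition or fingerprint tibble: id column, optional `sho`,
#'   then numeric variable columns.
#' @param center Mean-center variables (default `TRUE`).
#' @param scale Scale variables to unit variance (default `FALSE`; the raw
#'   quantities carry meaning and are analysed unscaled by default).
#' @return A `sho_pca` object: `loadings` (M x K, unit-norm columns),
#'   `scores` (N x K), `proportions`, `center`, `scale`, plus ids/labels.
#' @export
fit_pca <- function(df, center = TRUE, scale = FALSE) {
  X <- quantity_matrix(df)
  if (nrow(X) < 2) abort("PCA needs at least 2 rows.")
  if (scale) {
    sds <- apply(X, 2, sd)
    if (any(sds == 0)) {
      abort(sprintf("Constant column '%s' cannot be variance-scaled.",
                    colnames(X)[which(sds == 0)[1]]))
    }
  }
  pr <- prcomp(X, center = center, scale. = scale)
  # sign convention: largest-magnitude loading entry positive
  for (k in seq_len(ncol(pr$rotation))) {
    j <- which.max(abs(pr$rotation[, k]))
    if (pr$rotation[j, k] < 0) {
      pr$rotation[, k] <- -pr$rotation[, k]
      pr$x[, k] <- -pr$x[, k]
    }
  }
  ev <- pr$sdev^2
  structure(
    list(
      loadings = pr$rotation,
      scores = pr$x,
      sdev = pr$sdev,
      proportions = ev / sum(ev),
      center = if (isTRUE(center)) pr$center else rep(0, ncol(X)),
      scale = if (isTRUE(scale)) pr$scale else rep(1, ncol(X)),
      ids = rownames(X),
      sho = sho_of(df),
      variables = colnames(X)
    ),
    class = "sho_pca"
  )
}

#' @export
print.sho_pca <- function(x, ...) {
  cat(sprintf("<sho_pca> %d samples x %d variables, %d components\n",
              nrow(x$scores), nrow(x$loadings), ncol(x$scores)))
  k <- min(5, length(x$proportions))
  cat("  proportions:",
      paste(sprintf("PC%d %.1f%%", seq_len(k), 100 * x$proportions[seq_len(k)]),
            collapse = ", "), "...\n")
  invisible(x)
}

#' @rdname fit_pca
#' @param x,object A `sho_pca` object.
#' @param ... Unused.
#' @method tidy sho_pca
#' @export
tidy.sho_pca <- function(x, ...) {
  tibble::tibble(
    component = seq_along(x$proportions),
    variance = x$sdev^2,
    proportion = x$proportions,
    cumulative = cumsum(x$proportions)
  )
}

#' @rdname fit_pca
#' @method glance sho_pca
#' @export
glance.sho_pca <- function(x, ...) {
  tibble::tibble(
    n = nrow(x$scores),
    n_variables = nrow(x$loadings),
    n_components = ncol(x$scores),
    prop_pc1 = x$proportions[1]
  )
}

#' Factor loadings: correlation of scores with original variables
#'
#' The factor loading r(Z_k, X_j) is the Pearson correlation between the
#' k-th component score and the j-th original variable. Variables with
#' zero variance have undefined loadings and are returned as `NA`.
#'
#' @param pca A `sho_pca` fit.
#' @param df The table the fit was computed on.
#' @return Long tibble `component, variable, loading`.
#' @export
factor_loadings <- function(pca, df) {
  X <- quantity_matrix(df)
  if (!identical(colnames(X), pca$variables)) {
    abort("'df' does not match the variables the PCA was fitted on.")
  }
  sds <- apply(X, 2, sd)
  r <- suppressWarnings(cor(pca$scores, X))
  r[, sds == 0] <- NA_real_
  tibble::tibble(
    component = rep(seq_len(nrow(r)), times = ncol(r)),
    variable = rep(colnames(X), each = nrow(r)),
    loading = as.vector(r)
  )
}

#' @rdname factor_loadings
#' @param k Component index (1-based).
#' @param j Variable index or name.
#' @return `factor_loading()`: a single correlation in [-1, 1] (or `NA`
#'   for a constant variable).
#' @export
factor_loading <- function(pca, df, k, j) {
  X <- quantity_matrix(df)
  if (k < 1 || k > ncol(pca$scores)) abort("Component index out of range.")
  if (is.character(j)) j <- match(j, colnames(X))
  if (is.na(j) || j < 1 || j > ncol(X)) abort("Variable index out of range.")
  if (sd(X[, j]) == 0) return(NA_real_)
  cor(pca$scores[, k], X[, j])
}

#' Select the Sho-discriminating principal components
#'
#' Restricts to components explaining more than `variance_threshold` of
#' the variance (strictly), then tests each candidate's scores for a
#' Deficiency-vs-Excess location difference with a two-sided two-sample
#' t-test (Middle rows are excluded from the test, not the fit). The two
#' axes with the smallest p-values are chosen; ties break toward the
#' lower component index.
#'
#' @param pca A `sho_pca` fit.
#' @param labels Sho labels per row; defaults to those stored in the fit.
#' @param variance_threshold Minimum variance proportion for a candidate
#'   axis (default 0.01, i.e. components explaining > 1 %).
#' @param ttest `"welch"` (default, unequal variances) or `"pooled"`.
#' @return A `pc_selection` object: candidate tibble
#'   `component, proportion, p_value, statistic`, plus `chosen_axes`.
#' @export
select_discriminating_axes <- function(pca, labels = NULL,
                                       variance_threshold = 0.01,
                                       ttest = c("welch", "pooled")) {
  ttest <- match.arg(ttest)
  labels <- if (is.null(labels)) pca$sho else parse_sho(labels)
  if (is.null(labels)) abort("No Sho labels available for the t-tests.")
  if (length(labels) != nrow(pca$scores)) {
    abort("Label length does not match the number of scored rows.")
  }
  def <- labels == "Deficiency"
  exc <- labels == "Excess"
  if (sum(def) < 2 || sum(exc) < 2) {
    abort("Need at least 2 Deficiency and 2 Excess rows for the t-tests.")
  }
  cand <- which(pca$proportions > variance_threshold)
  if (length(cand) < 2) {
    abort(sprintf("Only %d axis(es) pass the %.3g variance filter; need >= 2.",
                  length(cand), variance_threshold))
  }
  tests <- purrr::map(cand, function(k) {
    t.test(pca$scores[def, k], pca$scores[exc, k],
           var.equal = (ttest == "pooled"))
  })
  res <- tibble::tibble(
    component = cand,
    proportion = pca$proportions[cand],
    statistic = purrr::map_dbl(tests, ~ unname(.x$statistic)),
    p_value = purrr::map_dbl(tests, "p.value")
  )
  chosen <- res$component[order(res$p_value, res$component)][1:2]
  structure(
    list(candidates = res, chosen_axes = chosen,
         variance_threshold = variance_threshold, ttest = ttest,
         total_candidate_variance = sum(res$proportion)),
    class = "pc_selection"
  )
}

#' @export
print.pc_selection <- function(x, ...) {
  cat(sprintf(
    "<pc_selection> %d candidate axes (> %.1f%% variance, %.1f%% total); chosen PC %d and PC %d\n",
    nrow(x$candidates), 100 * x$variance_threshold,
    100 * x$total_candidate_variance, x$chosen_axes[1], x$chosen_axes[2]))
  invisible(x)
}

#' @rdname select_discriminating_axes
#' @param x A `pc_selection` object.
#' @param ... Unused.
#' @method tidy pc_selection
#' @export
tidy.pc_selection <- function(x, ...) x$candidates

#' @rdname select_discriminating_axes
#' @method autoplot pc_selection
#' @export
autoplot.pc_selection <- function(x, ...) {
  d <- dplyr::mutate(x$candidates,
                     chosen = .data$component %in% x$chosen_axes)
  ggplot2::ggplot(d, ggplot2::aes(x = factor(.data$component),
                                  y = -log10(.data$p_value),
                                  fill = .data$chosen)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::labs(x = "Principal component",
                  y = expression(-log[10](italic(p))),
                  title = "Deficiency vs Excess separation per PC axis") +
    ggplot2::theme_minimal()
}

#' Project rows onto two principal component axes
#'
#' @param pca A `sho_pca` fit.
#' @param axes Pair of distinct 1-based component indices.
#' @return Tibble `id, sho, PC<a>, PC<b>` ready for plotting or export.
#' @export
project_scores <- function(pca, axes = c(1, 2)) {
  if (length(axes) != 2) abort("'axes' must be a pair of component indices.")
  if (axes[1] == axes[2]) abort("The two axes must be distinct.")
  if (any(axes < 1) || any(axes > ncol(pca$scores))) {
    abort("Axis index out of range.")
  }
  out <- tibble::tibble(
    id = pca$ids %||% as.character(seq_len(nrow(pca$scores))),
    a = unname(pca$scores[, axes[1]]),
    b = unname(pca$scores[, axes[2]])
  )
  names(out)[2:3] <- paste0("PC", axes)
  if (!is.null(pca$sho)) out <- dplyr::mutate(out, sho = pca$sho, .after = 1)
  out
}

#' Score plot on the two chosen axes
#'
#' @param x A `sho_pca` fit.
#' @param axes Pair of component indices (default the first two).
#' @param ... Unused.
#' @method autoplot sho_pca
#' @export
autoplot.sho_pca <- function(x, axes = c(1, 2), ...) {
  d <- project_scores(x, axes)
  nm <- paste0("PC", axes)
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data[[nm[1]]], y = .data[[nm[2]]]))
  if ("sho" %in% names(d)) {
    p <- p + ggplot2::geom_point(ggplot2::aes(colour = .data$sho, shape = .data$sho))
  } else {
    p <- p + ggplot2::geom_point()
  }
  p +
    ggplot2::labs(
      x = sprintf("%s (%.1f%%)", nm[1], 100 * x$proportions[axes[1]]),
      y = sprintf("%s (%.1f%%)", nm[2], 100 * x$proportions[axes[2]]),
      colour = "Sho", shape = "Sho"
    ) +
    ggplot2::theme_minimal()
}
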