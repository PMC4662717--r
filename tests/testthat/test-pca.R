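# PCA diagnostics against independent oracles: covariance
# eigendecomposition for the fit, manual Pearson sums for the factor
# loadings, and planted-structure recovery for the axis selection.

test_that("fit_pca agrees with a covariance eigendecomposition oracle", {
  set.seed(21)
  for (dims in list(c(5, 3), c(8, 8), c(10, 10), c(6, 9))) {
    n <- dims[1]; m <- dims[2]
    tbl <- random_formula_tbl(n, m, seed = n * 100 + m)
    p <- fit_pca(tbl)
    X <- shofactor:::quantity_matrix(tbl)
    eig <- eigen(cov(X), symmetric = TRUE)
    k <- ncol(p$scores)
    expect_equal(p$sdev^2, eig$values[seq_len(k)], tolerance = 1e-10)
    expect_equal(p$proportions,
                 eig$values[seq_len(k)] / sum(eig$values), tolerance = 1e-10)
    # loadings match up to sign where the eigenvalue is well separated
    gaps <- c(Inf, -diff(eig$values), Inf)
    for (j in seq_len(k)) {
      if (eig$values[j] < 1e-8 * eig$values[1]) next
      if (min(gaps[j], gaps[j + 1]) < 1e-6 * eig$values[1]) next
      d <- min(sqrt(sum((p$loadings[, j] - eig$vectors[, j])^2)),
               sqrt(sum((p$loadings[, j] + eig$vectors[, j])^2)))
      expect_lt(d, 1e-8)
    }
    expect_equal(sum(p$proportions), 1, tolerance = 1e-10)
    # unit-norm loadings, uncorrelated scores, exact reconstruction
    expect_equal(unname(colSums(p$loadings^2)), rep(1, k), tolerance = 1e-10)
    cv <- cov(p$scores)
    expect_lt(max(abs(cv[upper.tri(cv)])), 1e-8 * max(diag(cv)))
    Xc <- sweep(X, 2, colMeans(X), "-")
    expect_equal(unname(p$scores %*% t(p$loadings)), unname(Xc),
                 tolerance = 1e-8)
  }
})

test_that("closed 3x2 case and single-varying-column degeneracies", {
  tbl <- tibble::tibble(formula_id = c("a", "b", "c"),
                        sho = c("Deficiency", "Excess", "Deficiency"),
                        x = c(1, 0, -1), y = c(0, 1, 0))
  p <- fit_pca(tbl)
  ev <- eigen(cov(cbind(c(1, 0, -1), c(0, 1, 0))), symmetric = TRUE)$values
  expect_equal(p$proportions, ev / sum(ev), tolerance = 1e-12)

  one <- tibble::tibble(formula_id = c("a", "b", "c"), sho = "Middle",
                        varying = c(1, 2, 3), flat = c(5, 5, 5))
  p1 <- fit_pca(one)
  expect_equal(p1$proportions[1], 1.0)
  expect_equal(abs(factor_loading(p1, one, 1, "varying")), 1, tolerance = 1e-12)
  expect_true(is.na(factor_loading(p1, one, 1, "flat")))

  expect_error(fit_pca(one[1, ]), "at least 2")
  expect_error(fit_pca(one, scale = TRUE), "flat")
})

test_that("factor loadings equal an independent Pearson computation", {
  tbl <- random_formula_tbl(20, 5, seed = 77)
  p <- fit_pca(tbl)
  X <- shofactor:::quantity_matrix(tbl)
  fl <- factor_loadings(p, tbl)
  for (k in 1:4) {
    for (j in 1:5) {
      expect_equal(
        fl$loading[fl$component == k & fl$variable == colnames(X)[j]],
        manual_pearson(p$scores[, k], X[, j]),
        tolerance = 1e-10
      )
    }
  }
  expect_true(all(abs(fl$loading) <= 1 + 1e-12, na.rm = TRUE))
})

test_that("identical class score multisets give t = 0 and p = 1 on every axis", {
  base <- matrix(rnorm(5 * 4), 5, 4, dimnames = list(NULL, sprintf("v%d", 1:4)))
  tbl <- dplyr::bind_cols(
    tibble::tibble(formula_id = sprintf("F%d", 1:10),
                   sho = rep(c("Deficiency", "Excess"), 5)),
    tibble::as_tibble(base[rep(1:5, each = 2), ])
  )
  p <- fit_pca(tbl)
  sel <- select_discriminating_axes(p)
  expect_true(all(abs(sel$candidates$statistic) < 1e-8))
  expect_true(all(sel$candidates$p_value > 1 - 1e-8))
  # full tie: lower PC indices win
  expect_equal(sel$chosen_axes, c(1, 2))
})

test_that("the axis carrying a planted class shift is the top t-test pick", {
  gen <- generate_fingerprint_data(fingerprint_gen_config(
    n_samples = 60, grid = bin_grid(85, 134.5, 0.5),
    n_informative_bins = 20, class_shift = 80, noise_sd = 15, seed = 2
  ))
  p <- fit_pca(gen$data)
  sel <- select_discriminating_axes(p)
  hit <- ground_truth_report(gen$truth, sel, pca = p)
  expect_equal(hit$value, 1)
  # Welch vs pooled never changes the top-2 identity at this sample size
  sel_pooled <- select_discriminating_axes(p, ttest = "pooled")
  expect_equal(sort(sel$chosen_axes), sort(sel_pooled$chosen_axes))
})

test_that("axis selection guards its preconditions", {
  tbl <- random_formula_tbl(12, 4, seed = 5,
                            labels = rep(c("Deficiency", "Middle"), 6))
  p <- fit_pca(tbl)
  expect_error(select_discriminating_axes(p), "2 Deficiency and 2 Excess")
  p2 <- fit_pca(random_formula_tbl(12, 4, seed = 5))
  expect_error(select_discriminating_axes(p2, variance_threshold = 0.99),
               "variance filter")
})

test_that("2D projection returns labelled score pairs", {
  tbl <- random_formula_tbl(15, 6, seed = 12)
  p <- fit_pca(tbl)
  pr <- project_scores(p, c(1, 2))
  expect_equal(nrow(pr), 15)
  expect_named(pr, c("id", "sho", "PC1", "PC2"))
  expect_equal(pr$PC1, unname(p$scores[, 1]))
  expect_error(project_scores(p, c(3, 3)), "distinct")
  expect_error(project_scores(p, c(1, 99)), "range")
})
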