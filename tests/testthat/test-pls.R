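# NIPALS PLS1: algebraic identities (coefficient form vs component form,
# least-squares limit), Q-squared, component selection by cross-validated
# Q-squared, classification and the coefficient table.

test_that("label encoding maps Deficiency/Excess to -1/+1 and drops Middle", {
  enc <- encode_sho(c("Deficiency", "Middle", "Excess"))
  expect_equal(enc$y, c(-1, 1))
  expect_equal(enc$kept, c(1L, 3L))
  expect_equal(enc$n_dropped, 1L)
  expect_equal(encode_sho(c("Excess", "Deficiency"))$y, c(1, -1))
  expect_error(encode_sho(c("Middle", "Middle")), "at least one")
  expect_error(encode_sho(c("Deficiency", "Middle")), "at least one")
})

test_that("Q-squared identities and a hand-computed case", {
  y <- c(1, -1, 1, -1, 1)
  expect_equal(q_squared(y, y), 1)
  expect_equal(q_squared(y, rep(0, 5)), 0)  # uncentered denominator
  expect_equal(q_squared(c(1, -1, 1), c(0.5, -0.5, 0.5)), 1 - 0.75 / 3)
  expect_error(q_squared(c(0, 0), c(0, 0)), "All-zero")
  expect_error(q_squared(1:3, 1:2), "equal")
})

test_that("one component suffices when y is proportional to one column", {
  # mean-zero orthogonal columns (Helmert basis), so the first weight
  # vector points exactly along the informative column
  X <- stats::contr.helmert(12)[, 1:4]
  colnames(X) <- sprintf("d%02d", 1:4)
  tbl <- dplyr::bind_cols(
    tibble::tibble(formula_id = sprintf("F%03d", 1:12), sho = "Middle"),
    tibble::as_tibble(X))
  y <- 2 * X[, 1]
  fit <- fit_pls1(tbl, y = y, ncomp = 1)
  expect_lt(fit$e_norm[1] / sqrt(sum((y - mean(y))^2)), 1e-8)
})

test_that("PLS1 at full rank equals the least-squares oracle", {
  set.seed(8)
  tbl <- random_formula_tbl(8, 3, seed = 8)
  y <- rnorm(8)
  fit <- fit_pls1(tbl, y = y, ncomp = 3)
  X <- shofactor:::quantity_matrix(tbl)
  ols <- lm(y ~ X)
  expect_equal(fit$fitted, unname(fitted(ols)), tolerance = 1e-8)
  expect_equal(fit$b, unname(coef(ols)[-1]), tolerance = 1e-8)
})

test_that("duplicated correlated columns receive equal coefficients", {
  set.seed(17)
  u <- rnorm(20, 2)
  tbl <- tibble::tibble(formula_id = sprintf("F%d", 1:20),
                        sho = "Middle",
                        u = u, v = u, w = rnorm(20, 2))
  y <- u + rnorm(20, sd = 0.1)
  fit <- fit_pls1(tbl, y = y, ncomp = 2)
  expect_equal(fit$b[1], fit$b[2], tolerance = 1e-10)
})

test_that("coefficient-form and component-form predictions coincide", {
  tbl <- random_formula_tbl(25, 10, seed = 44)
  for (A in c(1, 3, 6)) {
    fit <- fit_pls1(tbl, ncomp = A)
    expect_lt(max(abs(fit$fitted - component_form_predict(fit, fit$X))), 1e-10)
    # and on unseen rows
    new <- shofactor:::quantity_matrix(random_formula_tbl(5, 10, seed = 45))
    pred <- unclass(predict(fit, random_formula_tbl(5, 10, seed = 45)))
    expect_lt(max(abs(pred$y_pred - component_form_predict(fit, new))), 1e-10)
  }
})

test_that("scores are orthogonal and deflation shrinks both residuals", {
  tbl <- random_formula_tbl(30, 12, seed = 55)
  fit <- fit_pls1(tbl, ncomp = 8)
  G <- crossprod(fit$scores)
  expect_lt(max(abs(G[upper.tri(G)])), 1e-8 * max(diag(G)))
  expect_true(all(diff(fit$E_norms) <= 1e-10))
  expect_true(all(diff(fit$e_norm) <= 1e-10))
})

test_that("in-sample Q2 never decreases with A but cross-validated Q2 can", {
  set.seed(66)
  gen <- generate_formula_data(formula_gen_config(
    n_formulas = 80, n_drugs = 25, effect_size = 0.15, seed = 66))
  de <- suppressMessages(subset_by_sho(gen$data, c("Deficiency", "Excess")))
  fit <- fit_pls1(de, ncomp = 12)
  expect_true(all(diff(fit$q2_insample) >= -1e-10))
  cv <- select_ncomp(de, a_max = 12)
  expect_true(any(diff(cv$curve$q2) < 0))
})

test_that("component selection recovers planted latent dimension", {
  # noiseless rank-1 data: one latent factor drives X and y, so the
  # first component explains everything and ties resolve to A* = 1
  set.seed(3)
  t_vec <- rnorm(20)
  X1 <- outer(t_vec, runif(6, 0.5, 2))
  colnames(X1) <- sprintf("d%02d", 1:6)
  tbl <- dplyr::bind_cols(
    tibble::tibble(formula_id = sprintf("F%03d", 1:20), sho = "Middle"),
    tibble::as_tibble(X1))
  cv1 <- select_ncomp(tbl, y = 1.5 * t_vec, a_max = 5)
  expect_lte(cv1$ncomp, 2)
  expect_gt(cv1$q2, 0.99)

  # three planted latent factors, mild noise: A* lands within 3 +/- 1
  set.seed(99)
  n <- 200; m <- 20
  Tm <- matrix(rnorm(n * 3), n, 3)
  P <- matrix(rnorm(m * 3), m, 3)
  X <- Tm %*% t(P) + matrix(rnorm(n * m, sd = 0.1), n, m)
  colnames(X) <- sprintf("v%02d", 1:m)
  tbl3 <- dplyr::bind_cols(tibble::tibble(formula_id = sprintf("F%d", 1:n),
                                          sho = "Middle"),
                           tibble::as_tibble(X))
  y3 <- as.vector(Tm %*% c(1, 0.8, 0.6)) + rnorm(n, sd = 0.2)
  cv3 <- select_ncomp(tbl3, y = y3, a_max = 8, cv = "kfold", kfold_k = 7)
  expect_gte(cv3$ncomp, 2)
  expect_lte(cv3$ncomp, 4)
})

test_that("prediction classifies by sign and reports the recognition rate", {
  gen <- generate_formula_data(formula_gen_config(
    n_formulas = 120, n_drugs = 40, seed = 10))
  de <- suppressMessages(subset_by_sho(gen$data, c("Deficiency", "Excess")))
  cv <- select_ncomp(de, a_max = 8)
  fit <- fit_pls1(de, ncomp = cv$ncomp)
  pred <- predict(fit, labels = ifelse(fit$y > 0, "Excess", "Deficiency"))
  expect_equal(pred$y_pred, fit$fitted)
  rr <- recognition_rate(pred)
  expect_equal(rr, sum(sign(pred$y_pred) == fit$y) / length(fit$y))
  expect_setequal(attr(pred, "misclassified"),
                  pred$id[sign(pred$y_pred) != fit$y])
  # an exact zero ties toward Excess
  expect_equal(shofactor:::sign_class(0), "Excess")
  expect_error(predict(fit, de[, 1:10]), "expects")
})

test_that("displayed rates use one decimal with half-up rounding", {
  expect_equal(shofactor:::format_pct(100 * 27 / 31), "87.1 %")
  expect_equal(shofactor:::format_pct(100 * 28 / 30), "93.3 %")
  expect_equal(shofactor:::format_pct(100 * 601 / 608), "98.8 %")
  expect_equal(shofactor:::format_pct(98.85), "98.9 %")
})

test_that("coefficient table filters, counts and sorts like a use-rate table", {
  set.seed(20)
  n <- 608
  present_a <- sample(n, 148); present_b <- sample(n, 429)
  tbl <- tibble::tibble(
    formula_id = sprintf("F%04d", 1:n),
    sho = rep(c("Deficiency", "Excess"), length.out = n),
    drug_a = ifelse(seq_len(n) %in% present_a, runif(n, 1, 3), 0),
    drug_b = ifelse(seq_len(n) %in% present_b, runif(n, 1, 3), 0),
    drug_c = runif(n, 1, 3)
  )
  fit <- fit_pls1(tbl, ncomp = 2)
  tab <- coefficient_table(fit, threshold = 0)
  expect_equal(tab$n_formulas[tab$drug == "drug_a"], 148L)
  expect_equal(tab$percentage[tab$drug == "drug_a"], 24.34)
  expect_equal(tab$n_formulas[tab$drug == "drug_b"], 429L)
  expect_equal(tab$percentage[tab$drug == "drug_b"], 70.56)
  # percentages stay consistent with counts
  expect_true(all(abs(tab$percentage - 100 * tab$n_formulas / n) <= 0.01))

  # threshold excludes small coefficients; blocks are sorted
  fake <- fit
  fake$b <- c(-0.25, 0.05, 0.18)
  tab2 <- coefficient_table(fake, threshold = 0.1)
  expect_false("drug_b" %in% tab2$drug)
  expect_equal(tab2$drug, c("drug_a", "drug_c"))
  expect_true(all(diff(tab2$b[tab2$b < 0]) >= 0))
})

test_that("exclusion refits reproduce the base run when nothing is excluded", {
  gen <- generate_formula_data(formula_gen_config(
    n_formulas = 60, n_drugs = 20, seed = 14))
  de <- suppressMessages(subset_by_sho(gen$data, c("Deficiency", "Excess")))
  base_cv <- select_ncomp(de)
  base_fit <- fit_pls1(de, ncomp = base_cv$ncomp)
  rerun <- refit_excluding(de, character(0))
  expect_equal(rerun$cv$ncomp, base_cv$ncomp)
  expect_equal(rerun$fit$b, base_fit$b)
  expect_error(refit_excluding(de, "NOPE"), "NOPE")
})

test_that("excluding a planted outlier cannot lower the recognition rate", {
  gen <- generate_formula_data(formula_gen_config(
    n_formulas = 80, n_drugs = 30, seed = 23))
  de <- suppressMessages(subset_by_sho(gen$data, c("Deficiency", "Excess")))
  # plant one mislabelled sample
  de$sho[1] <- ifelse(de$sho[1] == "Excess", "Deficiency", "Excess")
  base <- refit_excluding(de, character(0))
  excl <- refit_excluding(de, de$formula_id[1])
  expect_gte(recognition_rate(excl$prediction),
             recognition_rate(base$prediction))
})
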