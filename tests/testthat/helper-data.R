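# Small fixture builders used across the suite. Everything is generated
# in code; nothing is read from disk except files the tests write first.

tiny_formula_tbl <- function() {
  tibble::tibble(
    formula_id = c("F1", "F2", "F3"),
    sho = c("Deficiency", "Middle", "Excess"),
    ginger = c(2, 0, 1.5),
    licorice = c(0, 3, 1)
  )
}

# Random formula-style tibble with continuous positive quantities.
random_formula_tbl <- function(n, m, seed = 42, labels = NULL) {
  set.seed(seed)
  q <- matrix(abs(rnorm(n * m, 2, 1)), n, m,
              dimnames = list(NULL, sprintf("d%02d", seq_len(m))))
  if (is.null(labels)) {
    labels <- rep_len(c("Deficiency", "Excess"), n)
  }
  dplyr::bind_cols(
    tibble::tibble(formula_id = sprintf("F%03d", seq_len(n)), sho = labels),
    tibble::as_tibble(q)
  )
}

# Component-form PLS1 prediction, implemented independently of the
# package's coefficient-form predict(): center/scale the new rows, then
# walk the NIPALS deflation with the stored weights and loadings.
component_form_predict <- function(fit, X_new) {
  E <- sweep(sweep(X_new, 2, fit$x_mean, "-"), 2, fit$x_scale, "/")
  y_hat <- rep(fit$y_mean, nrow(X_new))
  for (k in seq_len(fit$A)) {
    t_k <- as.vector(E %*% fit$W[, k])
    y_hat <- y_hat + t_k * fit$q[k]
    E <- E - tcrossprod(t_k, fit$P[, k])
  }
  y_hat
}

# Manual Pearson correlation from the sum formulas (independent of
# stats::cor, which the implementation uses).
manual_pearson <- function(x, y) {
  n <- length(x)
  sx <- x - sum(x) / n
  sy <- y - sum(y) / n
  sum(sx * sy) / sqrt(sum(sx^2) * sum(sy^2))
}
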