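# Single-response partial least squares (PLS1) fitted by NIPALS, with the
# classification conventions used throughout: Deficiency coded -1, Excess
# coded +1, Middle dropped; prediction by the coefficient form
# y = b0 + sum_j b_j X_j; class read off the sign of the predicted y; the
# component count A chosen by maximizing the cross-validated Q^2 statistic
# Q^2 = 1 - sum (y_obs - y_pred)^2 / sum y_obs^2 (uncentered denominator,
# which equals N for a -1/+1 response).

#' Encode Sho labels as a -1/+1 response
#'
#' Deficiency becomes -1 and Excess becomes +1; Middle rows are dropped
#' and their positions recorded.
#'
#' @param labels Vector of Sho labels (any accepted spelling).
#' @return An `encoded_sho` list: `y` (values in -1/+1), `kept` (1-based
#'   indices of the retained rows), `n_dropped`.
#' @export
encode_sho <- function(labels) {
  lab <- parse_sho(labels)
  kept <- which(lab != "Middle")
  y <- ifelse(lab[kept] == "Excess", 1, -1)
  if (!any(y == -1) || !any(y == 1)) {
    abort("Need at least one Deficiency and one Excess row after dropping Middle.")
  }
  structure(list(y = as.double(y), kept = kept,
                 n_dropped = length(lab) - length(kept)),
            class = "encoded_sho")
}

# Resolve (df, y) into the modelling matrix and response. If y is NULL the
# table's own 'sho' column is encoded and Middle rows removed.
pls_design <- function(df, y = NULL) {
  if (is.null(y)) {
    if (!"sho" %in% names(df)) abort("No response: supply 'y' or a 'sho' column.")
    enc <- encode_sho(df$sho)
    df <- df[enc$kept, , drop = FALSE]
    y <- enc$y
  } else if (inherits(y, "encoded_sho")) {
    df <- df[y$kept, , drop = FALSE]
    y <- y$y
  } else {
    y <- as.double(y)
  }
  X <- quantity_matrix(df)
  if (length(y) != nrow(X)) abort("Response length does not match rows of X.")
  list(X = X, y = y, ids = rownames(X))
}

# Core NIPALS PLS1 decomposition on a centered (optionally scaled) X and
# centered y. Per component: weight w = E'f normalized to unit length,
# score t = E w, X-loading p = E't / t't, y-loading q = f't / t't, then
# deflation of both E and f. Returns everything needed to assemble the
# nested coefficient vectors b(a) for every a <= A.
nipals_pls1 <- function(X, y, A, scale = FALSE, tol = 1e-12, partial = FALSE) {
  N <- nrow(X); M <- ncol(X)
  if (var(y) == 0) abort("Response has zero variance.")
  if (A < 1) abort("Need at least one component.")
  if (A > min(N - 1, M)) {
    abort(sprintf("A = %d exceeds min(N - 1, M) = %d.", A, min(N - 1, M)))
  }
  x_mean <- colMeans(X)
  x_scale <- if (scale) apply(X, 2, sd) else rep(1, M)
  if (any(x_scale == 0)) {
    abort(sprintf("Constant column '%s' cannot be scaled.",
                  colnames(X)[which(x_scale == 0)[1]]))
  }
  y_mean <- mean(y)
  E <- sweep(sweep(X, 2, x_mean, "-"), 2, x_scale, "/")
  f <- y - y_mean
  ref <- sum(E^2)

  W <- P <- matrix(0, M, A)
  Tm <- matrix(0, N, A)
  q <- numeric(A)
  e_norm <- numeric(A)
  E_norms <- numeric(A)
  for (k in seq_len(A)) {
    w <- crossprod(E, f)
    nw <- sqrt(sum(w^2))
    if (nw^2 <= tol * max(ref, 1)) {
      # the X or y residual carries no further usable covariance
      if (partial) {
        A <- k - 1L
        W <- W[, seq_len(A), drop = FALSE]
        P <- P[, seq_len(A), drop = FALSE]
        Tm <- Tm[, seq_len(A), drop = FALSE]
        q <- q[seq_len(A)]
        e_norm <- e_norm[seq_len(A)]
        E_norms <- E_norms[seq_len(A)]
        break
      }
      abort(sprintf("Residual covariance is exhausted at component %d; A exceeds the effective rank.", k))
    }
    w <- w / nw
    t_k <- as.vector(E %*% w)
    tt <- sum(t_k^2)
    p <- as.vector(crossprod(E, t_k)) / tt
    q[k] <- sum(f * t_k) / tt
    E <- E - tcrossprod(t_k, p)
    f <- f - t_k * q[k]
    W[, k] <- w
    P[, k] <- p
    Tm[, k] <- t_k
    e_norm[k] <- sqrt(sum(f^2))
    E_norms[k] <- sqrt(sum(E^2))
  }
  list(W = W, P = P, q = q, scores = Tm,
       x_mean = x_mean, x_scale = x_scale, y_mean = y_mean,
       E_norm = sqrt(sum(E^2)), E_norms = E_norms, e_norm = e_norm)
}

# Coefficient vector on the original-variable scale for the first `a`
# components: b = W_a (P_a' W_a)^{-1} q_a (then undone for scaling), with
# intercept b0 = y_mean - x_mean' b.
pls_coefficients <- function(fit, a) {
  Wa <- fit$W[, seq_len(a), drop = FALSE]
  Pa <- fit$P[, seq_len(a), drop = FALSE]
  b_lat <- Wa %*% solve(crossprod(Pa, Wa), fit$q[seq_len(a)])
  b <- as.vector(b_lat) / fit$x_scale
  list(b = b, b0 = fit$y_mean - sum(fit$x_mean * b))
}

#' Fit a PLS1 discriminant model by NIPALS
#'
#' @param df Composition or fingerprint tibble (id column, optional `sho`,
#'   numeric variables). Middle rows are dropped when the response comes
#'   from the `sho` column.
#' @param y Optional response: an [encode_sho()] result or a numeric
#'   vector. When `NULL`, the table's `sho` column is encoded.
#' @param ncomp Number of latent components A.
#' @param scale Unit-variance scale the variables (default `FALSE`).
#' @return A `pls1_fit` with weights `W`, loadings `P`, y-loadings `q`,
#'   scores, means, coefficients `b`/`b0`, fitted values, residual norms
#'   and the in-sample Q-squared per component count.
#' @export
fit_pls1 <- function(df, y = NULL, ncomp, scale = FALSE) {
  d <- pls_design(df, y)
  fit <- nipals_pls1(d$X, d$y, ncomp, scale = scale)
  cf <- pls_coefficients(fit, ncomp)
  fitted <- cf$b0 + as.vector(d$X %*% cf$b)
  q2_in <- vapply(seq_len(ncomp), function(a) {
    ca <- pls_coefficients(fit, a)
    q_squared(d$y, ca$b0 + as.vector(d$X %*% ca$b))
  }, numeric(1))
  structure(
    c(fit, list(
      A = ncomp, scale = scale, b = cf$b, b0 = cf$b0,
      variables = colnames(d$X), ids = d$ids, y = d$y, X = d$X,
      fitted = fitted, q2_insample = q2_in
    )),
    class = "pls1_fit"
  )
}

#' @export
print.pls1_fit <- function(x, ...) {
  cat(sprintf("<pls1_fit> %d components, %d samples x %d variables; in-sample Q2 = %.3f\n",
              x$A, length(x$y), length(x$b), x$q2_insample[x$A]))
  invisible(x)
}

#' @rdname fit_pls1
#' @param x,object A `pls1_fit`.
#' @param ... Unused.
#' @method tidy pls1_fit
#' @export
tidy.pls1_fit <- function(x, ...) {
  tibble::tibble(term = x$variables, estimate = x$b)
}

#' @rdname fit_pls1
#' @method glance pls1_fit
#' @export
glance.pls1_fit <- function(x, ...) {
  tibble::tibble(
    n = length(x$y), n_variables = length(x$b), ncomp = x$A,
    q2_insample = x$q2_insample[x$A],
    recognition_rate = mean(sign_class(x$fitted) ==
                              ifelse(x$y > 0, "Excess", "Deficiency"))
  )
}

#' Predictive-fit statistic Q-squared
#'
#' `1 - sum((y_obs - y_pred)^2) / sum(y_obs^2)`. The denominator is
#' uncentered, so for a -1/+1 response it equals the sample count and a
#' constant-zero prediction scores exactly 0.
#'
#' @param y_obs Observed response.
#' @param y_pred Predicted response of the same length.
#' @return The Q-squared value (1 for a perfect prediction).
#' @export
q_squared <- function(y_obs, y_pred) {
  if (length(y_obs) != length(y_pred) || length(y_obs) < 1) {
    abort("'y_obs' and 'y_pred' must have equal, positive length.")
  }
  den <- sum(y_obs^2)
  if (den == 0) abort("All-zero 'y_obs': Q-squared is undefined.")
  1 - sum((y_obs - y_pred)^2) / den
}

sign_class <- function(y_pred) {
  # exact zero is a measure-zero tie, broken toward Excess and flagged
  ifelse(y_pred >= 0, "Excess", "Deficiency")
}

#' Predict Sho class from a fitted PLS1 model
#'
#' Uses the coefficient form `y = b0 + X b`. Negative predictions read as
#' Deficiency, positive as Excess; an exact zero is classified Excess and
#' flagged. When true labels are available the recognition rate (fraction
#' of non-Middle rows whose predicted sign matches the coded label) and
#' the misclassified ids are attached.
#'
#' @param object A `pls1_fit`.
#' @param newdata Tibble with the model's variable columns; defaults to
#'   the training table (in-sample prediction).
#' @param labels Optional Sho labels for `newdata`; defaults to its `sho`
#'   column if present, else (for in-sample use) the training response.
#' @param ... Unused.
#' @return A `sho_prediction` tibble `id, y_obs?, y_pred, predicted,
#'   correct?` with attributes `recognition_rate` and `misclassified`.
#' @export
predict.pls1_fit <- function(object, newdata = NULL, labels = NULL, ...) {
  if (is.null(newdata)) {
    X <- object$X
    ids <- object$ids
    y_obs <- object$y
  } else {
    X <- quantity_matrix(newdata)
    if (ncol(X) != length(object$b)) {
      abort(sprintf("newdata has %d variable columns; the model expects %d.",
                    ncol(X), length(object$b)))
    }
    if (!is.null(colnames(X)) && !is.null(object$variables) &&
        all(object$variables %in% colnames(X))) {
      X <- X[, object$variables, drop = FALSE]
    }
    ids <- rownames(X)
    y_obs <- NULL
    if (is.null(labels) && "sho" %in% names(newdata)) labels <- newdata$sho
  }
  if (!is.null(labels)) {
    lab <- parse_sho(labels)
    y_obs <- ifelse(lab == "Excess", 1, ifelse(lab == "Deficiency", -1, NA_real_))
  }
  y_pred <- object$b0 + as.vector(X %*% object$b)
  cls <- sign_class(y_pred)
  n_ties <- sum(y_pred == 0)
  if (n_ties > 0) {
    warn(sprintf("%d prediction(s) exactly 0; classified as Excess by convention.",
                 n_ties))
  }
  out <- tibble::tibble(
    id = ids %||% as.character(seq_along(y_pred)),
    y_pred = y_pred,
    predicted = cls
  )
  if (!is.null(y_obs)) {
    out <- dplyr::mutate(out, y_obs = y_obs, .after = 1)
    scored <- !is.na(y_obs)
    correct <- ifelse(scored, sign(ifelse(y_pred >= 0, 1, -1)) == y_obs, NA)
    out$correct <- correct
    attr(out, "recognition_rate") <- sum(correct[scored]) / sum(scored)
    attr(out, "misclassified") <- out$id[scored & !correct]
  }
  attr(out, "n_zero_ties") <- n_ties
  class(out) <- c("sho_prediction", class(out))
  out
}

#' @export
print.sho_prediction <- function(x, ...) {
  rr <- attr(x, "recognition_rate")
  NextMethod()
  if (!is.null(rr)) {
    cat(sprintf("Recognition rate: %s (%d misclassified)\n",
                format_pct(100 * rr), length(attr(x, "misclassified"))))
  }
  invisible(x)
}

#' Recognition rate of a prediction
#' @param pred A `sho_prediction`.
#' @return Fraction in [0, 1] of correctly sign-classified rows.
#' @export
recognition_rate <- function(pred) {
  rr <- attr(pred, "recognition_rate")
  if (is.null(rr)) abort("Prediction carries no true labels.")
  rr
}

#' Choose the PLS component count by cross-validated Q-squared
#'
#' For each candidate A from 1 to `a_max`, predictions for every row are
#' obtained from models fitted without that row (leave-one-out, the
#' default) or without its fold (stratified k-fold), and Q-squared is
#' computed from those held-out predictions. The selected A maximizes the
#' curve; ties break toward the smaller A.
#'
#' @param df Composition or fingerprint tibble.
#' @param y Optional response (see [fit_pls1()]).
#' @param a_max Largest component count tried; default
#'   `min(N - 1, M, 30)` (capped by what each training fold supports).
#' @param cv `"loo"` (default) or `"kfold"`.
#' @param kfold_k Number of folds for `cv = "kfold"` (default 7); folds
#'   are assigned round-robin within each class, so they are stratified
#'   and deterministic.
#' @param scale Passed to the per-fold fits.
#' @return A `pls_cv` list: `ncomp` (selected A), `q2` (its Q-squared),
#'   `curve` (tibble `ncomp, q2`), `cv_pred` (held-out predictions at the
#'   selected A).
#' @export
select_ncomp <- function(df, y = NULL, a_max = NULL,
                         cv = c("loo", "kfold"), kfold_k = 7, scale = FALSE) {
  cv <- match.arg(cv)
  d <- pls_design(df, y)
  N <- nrow(d$X); M <- ncol(d$X)
  folds <- if (cv == "loo") {
    as.list(seq_len(N))
  } else {
    stratified_folds(d$y, kfold_k)
  }
  max_train <- min(vapply(folds, function(i) N - length(i), numeric(1)))
  a_cap <- min(max_train - 1, M)
  a_max <- min(a_max %||% 30, N - 1, M, a_cap)
  if (a_max < 1) abort("Too few rows per fold to fit any component.")

  pred <- matrix(NA_real_, N, a_max)
  two_class <- all(d$y %in% c(-1, 1))
  for (fold in folds) {
    y_tr <- d$y[-fold]
    if (two_class && length(unique(y_tr)) < 2) {
      abort("A training fold contains a single class; use stratified k-fold CV.")
    }
    fit <- nipals_pls1(d$X[-fold, , drop = FALSE], y_tr, a_max, scale = scale,
                       partial = TRUE)
    a_fold <- ncol(fit$W)  # residual may be exhausted before a_max
    X_out <- d$X[fold, , drop = FALSE]
    for (a in seq_len(a_max)) {
      if (a_fold == 0) {
        pred[fold, a] <- fit$y_mean
      } else {
        ca <- pls_coefficients(fit, min(a, a_fold))
        pred[fold, a] <- ca$b0 + as.vector(X_out %*% ca$b)
      }
    }
  }
  q2 <- vapply(seq_len(a_max), function(a) q_squared(d$y, pred[, a]), numeric(1))
  a_star <- which.max(q2)  # first maximum = smallest A on ties
  structure(
    list(ncomp = a_star, q2 = q2[a_star],
         curve = tibble::tibble(ncomp = seq_len(a_max), q2 = q2),
         cv = cv, kfold_k = if (cv == "kfold") kfold_k else NA_integer_,
         cv_pred = pred[, a_star]),
    class = "pls_cv"
  )
}

stratified_folds <- function(y, k) {
  fold_id <- integer(length(y))
  for (cls in unique(sign(y))) {
    idx <- which(sign(y) == cls)
    fold_id[idx] <- rep_len(seq_len(k), length(idx))
  }
  unname(split(seq_along(y), fold_id))
}

#' @export
print.pls_cv <- function(x, ...) {
  cat(sprintf("<pls_cv> selected A = %d with cross-validated Q2 = %.3f (%s)\n",
              x$ncomp, x$q2, x$cv))
  invisible(x)
}

#' @rdname select_ncomp
#' @param x A `pls_cv` object.
#' @param ... Unused.
#' @method autoplot pls_cv
#' @export
autoplot.pls_cv <- function(x, ...) {
  ggplot2::ggplot(x$curve, ggplot2::aes(x = .data$ncomp, y = .data$q2)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_point(data = x$curve[x$curve$ncomp == x$ncomp, ],
                        colour = "red", size = 3) +
    ggplot2::labs(x = "Number of components A",
                  y = expression(Q^2),
                  title = "Cross-validated component selection") +
    ggplot2::theme_minimal()
}

#' Coefficient table of discriminating crude drugs
#'
#' Reports, per variable, the regression coefficient b, the number of
#' training formulas containing the drug (quantity > 0) and that count as
#' a percentage of N. Rows with |b| above the threshold are kept and laid
#' out with the negative (Deficiency-linked) block first, sorted
#' ascending, followed by the positive (Excess-linked) block sorted
#' descending.
#'
#' @param fit A `pls1_fit`.
#' @param threshold Keep rows with `|b| > threshold` (default 0.1).
#' @return Tibble `drug, b, n_formulas, percentage`.
#' @export
coefficient_table <- function(fit, threshold = 0.1) {
  N <- nrow(fit$X)
  tab <- tibble::tibble(
    drug = fit$variables,
    b = fit$b,
    n_formulas = unname(as.integer(colSums(fit$X > 0))),
    percentage = unname(round_half_up(100 * colSums(fit$X > 0) / N, 2))
  )
  tab <- dplyr::filter(tab, abs(.data$b) > threshold)
  neg <- dplyr::arrange(dplyr::filter(tab, .data$b < 0), .data$b)
  pos <- dplyr::arrange(dplyr::filter(tab, .data$b > 0), dplyr::desc(.data$b))
  dplyr::bind_rows(neg, pos)
}

#' Refit after excluding samples
#'
#' Removes the given ids, re-selects the component count by
#' cross-validation on the reduced set, refits, and reports the reduced
#' set's in-sample prediction. With an empty exclusion list this
#' reproduces the base run.
#'
#' @param df Composition or fingerprint tibble (with a `sho` column).
#' @param exclude_ids Character ids to drop (may be empty).
#' @param ... Passed to [select_ncomp()].
#' @return List `fit` (`pls1_fit`), `cv` (`pls_cv`), `prediction`
#'   (`sho_prediction`).
#' @export
refit_excluding <- function(df, exclude_ids = character(0), ...) {
  idc <- id_col_name(df)
  missing_ids <- setdiff(exclude_ids, df[[idc]])
  if (length(missing_ids) > 0) {
    abort(sprintf("Excluded id(s) not present: %s",
                  paste(missing_ids, collapse = ", ")))
  }
  sub <- df[!(df[[idc]] %in% exclude_ids), , drop = FALSE]
  cv <- select_ncomp(sub, ...)
  fit <- fit_pls1(sub, ncomp = cv$ncomp)
  pred <- predict(fit, labels = ifelse(fit$y > 0, "Excess", "Deficiency"))
  list(fit = fit, cv = cv, prediction = pred)
}
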