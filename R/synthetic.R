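# Synthetic data with planted Deficiency/Excess structure. The formula
# generator emulates a herbal-formula composition table: a sparse
# non-negative quantity matrix (around ten crude drugs per formula out of
# over a hundred), with class-linked usage of a few "effect" drugs, since
# in real formularies the signal sits in which drugs a class uses rather
# than in fine quantity differences. The fingerprint generator emulates a
# pre-binned direct-infusion intensity matrix with a class-linked mean
# shift planted in a subset of informative bins.

#' Configuration for the synthetic formula generator
#'
#' Defaults reflect the scale of a real formulary panel: 600 formulas over
#' 120 crude drugs, class frequencies matching an 826-formula registry
#' split of 382 Deficiency / 218 Middle / 226 Excess, about 10 drugs per
#' formula, gram-scale log-normal quantities, and 5 Excess-linked plus 5
#' Deficiency-linked effect drugs whose usage probability is boosted by
#' 0.35 in their class and suppressed in the opposite class.
#'
#' @param n_formulas,n_drugs Matrix dimensions N and M.
#' @param drugs_per_formula Length-2 range; its mean sets the base
#'   inclusion probability `mean(range)/n_drugs`.
#' @param n_effect_pos,n_effect_neg Number of Excess-linked (positive
#'   coefficient) and Deficiency-linked (negative) effect drugs.
#' @param effect_size Usage-probability boost/suppression for effect drugs
#'   in their own/opposite class, in [0, 1).
#' @param quantity_meanlog,quantity_sdlog Log-normal quantity parameters
#'   (defaults give gram-scale doses around 2.7 g).
#' @param class_proportions Named probabilities over
#'   Deficiency/Middle/Excess; must sum to 1.
#' @param label_noise Probability of flipping a Deficiency/Excess label.
#' @param seed Root seed; drives independent sub-streams for class draws,
#'   drug inclusion and quantities.
#' @return A `formula_gen_config` list.
#' @export
formula_gen_config <- function(n_formulas = 600, n_drugs = 120,
                               drugs_per_formula = c(6, 14),
                               n_effect_pos = 5, n_effect_neg = 5,
                               effect_size = 0.35,
                               quantity_meanlog = 1, quantity_sdlog = 0.5,
                               class_proportions = c(Deficiency = 382, Middle = 218, Excess = 226) / 826,
                               label_noise = 0, seed = 1) {
  if (length(drugs_per_formula) != 2 || any(drugs_per_formula < 1)) {
    abort("'drugs_per_formula' must be a positive length-2 range.")
  }
  if (max(drugs_per_formula) > n_drugs) {
    abort("'drugs_per_formula' cannot exceed 'n_drugs'.")
  }
  if (n_effect_pos + n_effect_neg > n_drugs) {
    abort("More effect drugs than drugs.")
  }
  if (abs(sum(class_proportions) - 1) > 1e-8) {
    abort("'class_proportions' must sum to 1.")
  }
  if (effect_size < 0 || effect_size >= 1) abort("'effect_size' must be in [0, 1).")
  if (label_noise < 0 || label_noise >= 1) abort("'label_noise' must be in [0, 1).")
  structure(as.list(environment()), class = "formula_gen_config")
}

# Derive independent sub-stream seeds from the root seed, so toggling one
# generation mechanism leaves the draws of the others unchanged.
sub_seeds <- function(seed, n) {
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}

#' Generate a synthetic formula composition table
#'
#' Each formula draws its class from `class_proportions`; each drug is
#' included with a base Bernoulli rate, boosted by `effect_size` for
#' effect drugs in their class and suppressed toward 0 in the opposite
#' class; included drugs receive log-normal quantities. Fully
#' deterministic under the config seed.
#'
#' @param config A [formula_gen_config()].
#' @return List with `data` (a validated composition tibble) and `truth`
#'   (tibble `drug, effect_sign` with +1 for Excess-linked and -1 for
#'   Deficiency-linked effect drugs, 0 otherwise).
#' @export
generate_formula_data <- function(config = formula_gen_config()) {
  stopifnot(inherits(config, "formula_gen_config"))
  N <- config$n_formulas; M <- config$n_drugs
  ss <- sub_seeds(config$seed, 3)
  drugs <- sprintf("drug_%03d", seq_len(M))

  set.seed(ss[1])
  cls <- sample(sho_levels(), N, replace = TRUE, prob = config$class_proportions)
  if (config$label_noise > 0) {
    de <- which(cls != "Middle")
    flip <- de[runif(length(de)) < config$label_noise]
    cls[flip] <- ifelse(cls[flip] == "Excess", "Deficiency", "Excess")
  }

  set.seed(ss[2])
  eff_idx <- sample.int(M, config$n_effect_pos + config$n_effect_neg)
  pos_idx <- eff_idx[seq_len(config$n_effect_pos)]
  neg_idx <- setdiff(eff_idx, pos_idx)
  effect_sign <- integer(M)
  effect_sign[pos_idx] <- 1L
  effect_sign[neg_idx] <- -1L
  p0 <- mean(config$drugs_per_formula) / M
  prob <- matrix(p0, N, M)
  boost <- config$effect_size
  prob[cls == "Excess", pos_idx] <- min(1, p0 + boost)
  prob[cls == "Deficiency", pos_idx] <- max(0, p0 - boost)
  prob[cls == "Deficiency", neg_idx] <- min(1, p0 + boost)
  prob[cls == "Excess", neg_idx] <- max(0, p0 - boost)
  incl <- matrix(runif(N * M), N, M) < prob

  set.seed(ss[3])
  qty <- matrix(0, N, M, dimnames = list(NULL, drugs))
  qty[incl] <- rlnorm(sum(incl), config$quantity_meanlog, config$quantity_sdlog)

  data <- dplyr::bind_cols(
    tibble::tibble(formula_id = sprintf("F%04d", seq_len(N)), sho = cls),
    tibble::as_tibble(qty)
  )
  list(
    data = as_formula_tbl(data),
    truth = tibble::tibble(drug = drugs, effect_sign = effect_sign)
  )
}

#' Configuration for the synthetic fingerprint generator
#'
#' Defaults mirror a 34-sample direct-infusion panel (19 Deficiency, 3
#' Middle, 12 Excess) on the standard 2,230-bin grid, with 50 informative
#' bins carrying a class-linked mean shift over a noisy baseline.
#'
#' @param n_samples Number of spectra.
#' @param grid A [bin_grid()].
#' @param n_informative_bins Bins carrying the planted class shift.
#' @param class_shift Mean intensity offset between Excess and Deficiency
#'   in informative bins (arbitrary counts).
#' @param noise_sd Gaussian noise standard deviation.
#' @param baseline_intensity Mean background intensity.
#' @param class_proportions Named probabilities over the three classes.
#' @param seed Root seed.
#' @return A `fingerprint_gen_config` list.
#' @export
fingerprint_gen_config <- function(n_samples = 34, grid = bin_grid(),
                                   n_informative_bins = 50,
                                   class_shift = 60, noise_sd = 20,
                                   baseline_intensity = 100,
                                   class_proportions = c(Deficiency = 19, Middle = 3, Excess = 12) / 34,
                                   seed = 1) {
  if (!inherits(grid, "bin_grid")) abort("'grid' must be a bin_grid.")
  if (n_informative_bins > n_bins(grid)) {
    abort("More informative bins than bins in the grid.")
  }
  if (noise_sd < 0) abort("'noise_sd' must be non-negative.")
  if (abs(sum(class_proportions) - 1) > 1e-8) {
    abort("'class_proportions' must sum to 1.")
  }
  structure(as.list(environment()), class = "fingerprint_gen_config")
}

#' Generate a synthetic fingerprint matrix
#'
#' Intensities are baseline plus Gaussian noise, clipped at zero; the
#' informative bins additionally carry +shift/2 for Excess and -shift/2
#' for Deficiency samples (each informative bin's direction is drawn at
#' random and recorded in the truth).
#'
#' @param config A [fingerprint_gen_config()].
#' @return List with `data` (fingerprint tibble with labels) and `truth`
#'   (`informative` tibble of bin name/index/direction, plus the per-bin
#'   class contrast vector `delta` over all bins).
#' @export
generate_fingerprint_data <- function(config = fingerprint_gen_config()) {
  stopifnot(inherits(config, "fingerprint_gen_config"))
  n <- config$n_samples
  B <- n_bins(config$grid)
  ss <- sub_seeds(config$seed, 3)

  set.seed(ss[1])
  cls <- sample(sho_levels(), n, replace = TRUE, prob = config$class_proportions)

  set.seed(ss[2])
  info_idx <- sort(sample.int(B, config$n_informative_bins))
  direction <- sample(c(-1, 1), config$n_informative_bins, replace = TRUE)
  delta <- numeric(B)
  delta[info_idx] <- direction * config$class_shift

  set.seed(ss[3])
  m <- matrix(rnorm(n * B, config$baseline_intensity, config$noise_sd), n, B)
  class_sign <- ifelse(cls == "Excess", 0.5, ifelse(cls == "Deficiency", -0.5, 0))
  m <- m + outer(class_sign, delta)
  m <- pmax(m, 0)
  colnames(m) <- bin_col_names(config$grid)

  data <- dplyr::bind_cols(
    tibble::tibble(sample_id = sprintf("S%02d", seq_len(n)),
                   sho = parse_sho(cls)),
    tibble::as_tibble(m)
  )
  attr(data, "grid") <- config$grid
  list(
    data = data,
    truth = list(
      informative = tibble::tibble(
        bin = colnames(m)[info_idx], index = info_idx, direction = direction),
      delta = delta
    )
  )
}

#' Recovery metrics against the planted ground truth
#'
#' For a `pls1_fit`, the fraction of effect drugs whose coefficient sign
#' matches the planted sign. For a `pc_selection` over a fingerprint fit,
#' whether the top-picked axis is the axis whose loadings align best with
#' the planted class contrast (identified independently of the t-tests by
#' maximal absolute correlation between candidate loadings and the
#' contrast vector). For a `sho_prediction`, the recognition rate.
#'
#' @param truth The truth record returned by a generator.
#' @param model A `pls1_fit`, `pc_selection` (paired with its `sho_pca`
#'   via `pca =`), or `sho_prediction`.
#' @param pca The `sho_pca` fit, required for `pc_selection` scoring.
#' @return A tibble of metrics, each in [0, 1].
#' @export
ground_truth_report <- function(truth, model, pca = NULL) {
  if (inherits(model, "pls1_fit")) {
    tr <- if (is.data.frame(truth)) truth else truth$truth
    eff <- tr[tr$effect_sign != 0, ]
    b <- model$b[match(eff$drug, model$variables)]
    if (anyNA(b)) abort("Truth drugs not found in the fitted model.")
    return(tibble::tibble(metric = "sign_recovery",
                          value = mean(sign(b) == eff$effect_sign)))
  }
  if (inherits(model, "pc_selection")) {
    if (is.null(pca)) abort("Scoring a pc_selection needs the 'pca' fit.")
    tr <- if (is.list(truth) && !is.data.frame(truth)) truth else list(truth = truth)
    delta <- tr$delta %||%
      (if (is.data.frame(tr$truth) && "effect_sign" %in% names(tr$truth))
        as.numeric(tr$truth$effect_sign) else tr$truth$delta)
    if (is.null(delta) || length(delta) != nrow(pca$loadings)) {
      abort("Truth contrast length does not match the fitted variables.")
    }
    cand <- model$candidates$component
    align <- vapply(cand, function(k) abs(cor(pca$loadings[, k], delta)),
                    numeric(1))
    planted <- cand[which.max(align)]
    return(tibble::tibble(metric = "axis_hit",
                          value = as.numeric(model$chosen_axes[1] == planted)))
  }
  if (inherits(model, "sho_prediction")) {
    return(tibble::tibble(metric = "recognition_rate",
                          value = recognition_rate(model)))
  }
  abort("Unsupported model type for ground_truth_report().")
}
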