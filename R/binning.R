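# Fixed-width m/z binning of direct-infusion spectra into fingerprint
# matrices. The default grid (85.0 to 1199.5 in steps of 0.5) has 2,230
# bins, matching positive-ESI acquisition over m/z 85-1200.

#' Construct a fixed-width m/z bin grid
#'
#' Bin `b` covers the half-open interval `[edge_b, edge_b + width)`; the
#' last bin therefore reaches `hi + width` exclusive (at the defaults,
#' `[1199.5, 1200)`, the acquisition ceiling).
#'
#' @param lo Lowest bin edge (default 85.0).
#' @param hi Highest bin edge, inclusive (default 1199.5).
#' @param width Bin width in m/z units (default 0.5).
#' @return A `bin_grid` object with the ordered lower edges.
#' @examples
#' n_bins(bin_grid())  # 2230
#' @export
bin_grid <- function(lo = 85.0, hi = 1199.5, width = 0.5) {
  if (!(lo < hi)) abort("'lo' must be strictly below 'hi'.")
  if (width <= 0) abort("'width' must be positive.")
  k <- (hi - lo) / width
  if (abs(k - round(k)) > 1e-9) {
    abort(sprintf("(hi - lo) = %g is not an integer multiple of width = %g.",
                  hi - lo, width))
  }
  k <- as.integer(round(k))
  structure(
    list(lo = lo, hi = hi, width = width, edges = lo + width * (0:k)),
    class = "bin_grid"
  )
}

#' @export
print.bin_grid <- function(x, ...) {
  cat(sprintf("<bin_grid> %d bins of width %g over m/z [%g, %g]\n",
              n_bins(x), x$width, x$lo, x$hi))
  invisible(x)
}

#' Number of bins in a grid
#' @param grid A `bin_grid`.
#' @return Integer bin count.
#' @export
n_bins <- function(grid) length(grid$edges)

bin_col_names <- function(grid) {
  paste0("mz_", sub("\\.?0+$", "", sprintf("%.2f", grid$edges)))
}

#' Bin one spectrum onto a grid
#'
#' Sums centroided peak intensities into the half-open bin containing each
#' peak's m/z. Peaks outside `[lo, hi + width)` are discarded; the count of
#' discarded peaks is attached as attribute `n_discarded` and reported.
#'
#' @param peaks Data frame with numeric columns `mz` (> 0) and
#'   `intensity` (>= 0).
#' @param grid A `bin_grid`.
#' @return Numeric vector of integrated intensities, one per bin, named by
#'   bin edge.
#' @export
bin_spectrum <- function(peaks, grid = bin_grid()) {
  peaks <- tibble::as_tibble(peaks)
  if (!all(c("mz", "intensity") %in% names(peaks))) {
    abort("'peaks' needs 'mz' and 'intensity' columns.")
  }
  if (nrow(peaks) > 0) {
    if (any(peaks$mz <= 0)) abort("All m/z values must be positive.")
    if (any(peaks$intensity < 0)) abort("Peak intensities must be non-negative.")
  }
  B <- n_bins(grid)
  out <- setNames(numeric(B), bin_col_names(grid))
  if (nrow(peaks) == 0) {
    attr(out, "n_discarded") <- 0L
    return(out)
  }
  # small forward nudge so edge-exact m/z values land in their own bin
  idx <- floor((peaks$mz - grid$lo) / grid$width + 1e-9) + 1
  in_range <- idx >= 1 & idx <= B
  n_disc <- sum(!in_range)
  if (n_disc > 0) {
    inform(sprintf("Discarded %d peak(s) outside m/z [%g, %g).",
                   n_disc, grid$lo, grid$hi + grid$width))
  }
  acc <- vapply(
    split(peaks$intensity[in_range], factor(idx[in_range], levels = seq_len(B))),
    sum, numeric(1)
  )
  out[] <- unname(acc)
  attr(out, "n_discarded") <- as.integer(n_disc)
  out
}

#' Build a fingerprint matrix from many spectra
#'
#' @param peaks Long-format tibble with columns `sample_id`, `mz`,
#'   `intensity` (one row per peak), or a named list of per-sample peak
#'   data frames.
#' @param grid A `bin_grid`.
#' @param labels Optional tibble `sample_id, sho` attaching class labels.
#' @return Fingerprint tibble: `sample_id`, optional `sho`, then one
#'   intensity column per bin.
#' @export
build_fingerprint_matrix <- function(peaks, grid = bin_grid(), labels = NULL) {
  if (is.data.frame(peaks)) {
    if (!"sample_id" %in% names(peaks)) {
      abort("Long-format peaks need a 'sample_id' column.")
    }
    peaks <- split(peaks[c("mz", "intensity")], peaks$sample_id)
  }
  if (length(peaks) == 0) abort("No spectra supplied.")
  ids <- names(peaks)
  if (is.null(ids) || anyDuplicated(ids) || any(ids == "")) {
    abort("Spectra must carry unique, non-empty sample ids.")
  }
  rows <- purrr::map(peaks, function(p) {
    suppressMessages(bin_spectrum(p, grid))
  })
  fp <- tibble::as_tibble(do.call(rbind, rows))
  fp <- dplyr::bind_cols(tibble::tibble(sample_id = ids), fp)
  attach_labels(fp, labels, grid)
}

attach_labels <- function(fp, labels, grid) {
  if (!is.null(labels)) {
    labels <- tibble::as_tibble(labels)
    if (!all(c("sample_id", "sho") %in% names(labels))) {
      abort("'labels' needs 'sample_id' and 'sho' columns.")
    }
    labels$sample_id <- as.character(labels$sample_id)
    unknown <- setdiff(labels$sample_id, fp$sample_id)
    if (length(unknown) > 0) {
      warn(sprintf("Label file names %d sample(s) not in the matrix: %s",
                   length(unknown), paste(head(unknown, 5), collapse = ", ")))
    }
    lab <- labels$sho[match(fp$sample_id, labels$sample_id)]
    fp <- dplyr::bind_cols(fp[1], tibble::tibble(sho = parse_sho(lab)),
                           fp[-1])
  }
  attr(fp, "grid") <- grid
  fp
}

#' Read a pre-binned intensity matrix
#'
#' Accepts CSV/TSV (and XLSX when the readxl package is installed) in
#' either orientation: bins as rows with samples as columns, or samples as
#' rows with bins as columns. The orientation is detected by finding the
#' arithmetic 0.5-step m/z edge signature, and the grid is reconstructed
#' from the edge values.
#'
#' @param path Path to the matrix file.
#' @param labels Optional label sidecar: a path to a `sample_id,sho` CSV or
#'   a tibble in that layout.
#' @return Fingerprint tibble as from [build_fingerprint_matrix()].
#' @export
read_binned_matrix <- function(path, labels = NULL) {
  if (!file.exists(path)) abort(sprintf("File not found: '%s'.", path))
  if (grepl("\\.xlsx?$", path, ignore.case = TRUE)) {
    if (!requireNamespace("readxl", quietly = TRUE)) {
      abort("Reading XLSX requires the 'readxl' package; supply CSV instead.")
    }
    raw <- tibble::as_tibble(readxl::read_excel(path))
  } else {
    delim <- if (grepl("\\.tsv$|\\.txt$", path, ignore.case = TRUE)) "\t" else ","
    raw <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                             progress = FALSE, name_repair = "minimal")
  }
  if (is.character(labels)) {
    labels <- readr::read_csv(labels, show_col_types = FALSE, progress = FALSE)
  }

  first_col <- suppressWarnings(as.numeric(raw[[1]]))
  header_vals <- suppressWarnings(as.numeric(names(raw)[-1]))
  if (!any(is.na(first_col)) && is_edge_seq(first_col)) {
    # rows are bins, columns are samples -> transpose
    edges <- first_col
    ids <- names(raw)[-1]
    m <- t(as.matrix(raw[-1]))
  } else if (!any(is.na(header_vals)) && is_edge_seq(header_vals)) {
    edges <- header_vals
    ids <- as.character(raw[[1]])
    m <- as.matrix(raw[-1])
  } else {
    abort("Could not find an arithmetic m/z edge sequence with step 0.5 in rows or columns.")
  }
  storage.mode(m) <- "double"
  grid <- bin_grid(lo = min(edges), hi = max(edges), width = 0.5)
  fp <- tibble::as_tibble(m, .name_repair = "minimal")
  names(fp) <- bin_col_names(grid)
  fp <- dplyr::bind_cols(tibble::tibble(sample_id = ids), fp)
  attach_labels(fp, labels, grid)
}

is_edge_seq <- function(x, step = 0.5, tol = 1e-6) {
  length(x) >= 2 && all(abs(diff(x) - step) < tol)
}

#' Total-ion-current normalization of a fingerprint matrix
#'
#' Divides each sample's intensities by their total, so every row sums
#' to 1. Off by default in the pipeline (the binned intensities are
#' analysed raw); provided as optional preprocessing.
#'
#' @param fp Fingerprint tibble.
#' @return Fingerprint tibble with row-normalized intensities.
#' @export
tic_normalize <- function(fp) {
  m <- quantity_matrix(fp)
  tot <- rowSums(m)
  if (any(tot <= 0)) {
    bad <- rownames(m)[which(tot <= 0)[1]]
    abort(sprintf("Sample '%s' has zero total intensity; cannot normalize.", bad))
  }
  meta <- meta_col_names(fp)
  out <- dplyr::bind_cols(fp[meta],
                          tibble::as_tibble(sweep(m, 1, tot, "/")))
  attr(out, "grid") <- attr(fp, "grid")
  out
}
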