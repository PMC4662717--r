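#' Validate a formula composition table
#'
#' A composition table is a tibble with one row per herbal formula: a
#' `formula_id` column (unique identifiers), a `sho` column (Deficiency,
#' Middle or Excess; the romanized aliases Kyo/Kang/Jitsu are accepted),
#' and one non-negative numeric column per crude drug holding the quantity
#' (grams or relative parts) of that drug in the formula. An absent drug
#' is encoded as 0, never as missing.
#'
#' @param df A data frame in the layout above.
#' @return A validated tibble with `sho` as a factor over the three states.
#' @export
as_formula_tbl <- function(df) {
  df <- tibble::as_tibble(df)
  if (!all(c("formula_id", "sho") %in% names(df))) {
    abort("A formula table needs 'formula_id' and 'sho' columns.")
  }
  df$formula_id <- as.character(df$formula_id)
  if (anyDuplicated(df$formula_id)) {
    dup <- df$formula_id[duplicated(df$formula_id)][1]
    abort(sprintf("Duplicate formula_id '%s'.", dup))
  }
  df$sho <- parse_sho(df$sho)
  drugs <- setdiff(names(df), c("formula_id", "sho"))
  if (anyDuplicated(drugs)) abort("Drug column names must be unique.")
  for (d in drugs) {
    v <- df[[d]]
    if (!is.numeric(v)) abort(sprintf("Drug column '%s' is not numeric.", d))
    v[is.na(v)] <- 0  # blank cell = drug absent
    if (any(v < 0)) {
      i <- which(v < 0)[1]
      abort(sprintf("Negative quantity %g in row %d (formula '%s'), drug '%s'.",
                    v[i], i, df$formula_id[i], d))
    }
    df[[d]] <- as.double(v)
  }
  df[c("formula_id", "sho", drugs)]
}

#' Read a formula composition table from CSV/TSV
#'
#' The dialect is `formula_id,sho,<drug1>,<drug2>,...` with one header row
#' naming the crude drugs. Blank quantity cells are read as 0.
#'
#' @param path Path to a `.csv` or `.tsv`/`.txt` file.
#' @return A validated composition tibble (see [as_formula_tbl()]).
#' @export
read_formula_table <- function(path) {
  if (!file.exists(path)) abort(sprintf("File not found: '%s'.", path))
  delim <- if (grepl("\\.tsv$|\\.txt$", path, ignore.case = TRUE)) "\t" else ","
  # quantities are read as text and converted with strtod so that the
  # write -> read round trip reproduces every double bit-exactly
  df <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                          progress = FALSE, name_repair = "minimal",
                          col_types = readr::cols(.default = "c"))
  names(df)[1:2] <- c("formula_id", "sho")
  for (j in setdiff(names(df), c("formula_id", "sho"))) {
    raw <- df[[j]]
    val <- suppressWarnings(as.numeric(raw))
    bad <- which(is.na(val) & !is.na(raw) & trimws(raw) != "")
    if (length(bad) > 0) {
      abort(sprintf("Non-numeric quantity '%s' in row %d, drug '%s'.",
                    raw[bad[1]], bad[1], j))
    }
    df[[j]] <- val
  }
  as_formula_tbl(df)
}

#' Write a formula composition table as CSV
#'
#' Writes the dialect [read_formula_table()] accepts, so that
#' write-then-read reproduces quantities and labels exactly.
#'
#' @param df A validated composition tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_formula_table <- function(df, path) {
  df <- as_formula_tbl(df)
  readr::write_csv(df, path, progress = FALSE)
  invisible(path)
}

#' Restrict a composition table to chosen Sho classes
#'
#' Used before two-class discriminant modelling, where Middle formulas are
#' dropped. Optionally also drops crude-drug columns that become all-zero
#' after row filtering (the surviving drug count shrinks the same way the
#' modelled variable set shrinks when a class is excluded); dropped names
#' are recorded in the `dropped_drugs` attribute.
#'
#' @param df A composition tibble.
#' @param keep Character vector of Sho classes to keep.
#' @param drop_empty_drugs Drop all-zero drug columns after filtering
#'   (default `TRUE`).
#' @return The filtered tibble, with attribute `dropped_drugs`.
#' @export
subset_by_sho <- function(df, keep = c("Deficiency", "Excess"),
                          drop_empty_drugs = TRUE) {
  df <- as_formula_tbl(df)
  if (length(keep) == 0) abort("'keep' must name at least one Sho class.")
  keep <- as.character(parse_sho(keep, context = "class"))
  out <- dplyr::filter(df, as.character(.data$sho) %in% keep)
  if (nrow(out) == 0) abort("no formulas after filtering")
  dropped <- character(0)
  if (drop_empty_drugs) {
    drugs <- setdiff(names(out), c("formula_id", "sho"))
    empty <- drugs[vapply(out[drugs], function(v) all(v == 0), logical(1))]
    if (length(empty) > 0) {
      out <- out[setdiff(names(out), empty)]
      dropped <- empty
      inform(sprintf("Dropped %d all-zero drug column(s) after filtering: %s",
                     length(empty), paste(head(empty, 5), collapse = ", ")))
    }
  }
  attr(out, "dropped_drugs") <- dropped
  out
}
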