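# Shared helpers: label parsing, tibble <-> matrix plumbing, formatting.

sho_levels <- function() c("Deficiency", "Middle", "Excess")

# Case-insensitive parse of Sho labels; accepts the romanized Japanese
# aliases Kyo/Kang/Jitsu. Returns a factor with the canonical three levels.
parse_sho <- function(x, context = "label") {
  x_chr <- trimws(as.character(x))
  key <- tolower(x_chr)
  map <- c(
    deficiency = "Deficiency", kyo = "Deficiency",
    middle = "Middle", kang = "Middle",
    excess = "Excess", jitsu = "Excess"
  )
  out <- unname(map[key])
  bad <- which(is.na(out) & !is.na(x_chr))
  if (length(bad) > 0) {
    abort(sprintf(
      "Unknown Sho %s '%s' in row %d (expected Deficiency/Middle/Excess or Kyo/Kang/Jitsu).",
      context, x_chr[bad[1]], bad[1]
    ))
  }
  factor(out, levels = sho_levels())
}

# Columns that carry identifiers/labels rather than quantities.
meta_col_names <- function(df) intersect(c("formula_id", "sample_id", "sho"), names(df))

id_col_name <- function(df) {
  id <- intersect(c("formula_id", "sample_id"), names(df))
  if (length(id) == 0) abort("Data must have a 'formula_id' or 'sample_id' column.")
  id[1]
}

# Extract the numeric quantity block of a composition/fingerprint tibble
# as a dense matrix with sample ids as rownames.
quantity_matrix <- function(df) {
  meta <- meta_col_names(df)
  vars <- setdiff(names(df), meta)
  if (length(vars) == 0) {
    m <- matrix(numeric(0), nrow = nrow(df), ncol = 0)
  } else {
    ok <- vapply(df[vars], is.numeric, logical(1))
    if (!all(ok)) {
      abort(sprintf("Non-numeric quantity column(s): %s.",
                    paste(vars[!ok], collapse = ", ")))
    }
    m <- as.matrix(df[vars])
    storage.mode(m) <- "double"
  }
  rownames(m) <- as.character(df[[id_col_name(df)]])
  m
}

sho_of <- function(df) {
  if (!"sho" %in% names(df)) return(NULL)
  parse_sho(df$sho)
}

# Round half up (so 87.05 -> 87.1), the convention used for displayed rates.
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

format_pct <- function(x, digits = 1) {
  sprintf(paste0("%.", digits, "f %%"), round_half_up(x, digits))
}
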