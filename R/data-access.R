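#' Sho labels of the 34-prescription direct-infusion panel
#'
#' The published class assignments (19 Deficiency, 3 Middle, 12 Excess) of
#' the 34 cinnamon-bark-centred Kampo prescriptions profiled by
#' direct-infusion MS, shipped as a label sidecar. The intensity matrix
#' itself is not redistributed; pair these labels with your own binned
#' matrix or a synthetic stand-in from
#' [generate_fingerprint_data()].
#'
#' @return Tibble `sample_id, prescription_no, sho`.
#' @export
kampo34_labels <- function() {
  path <- system.file("extdata", "kampo34_labels.csv", package = "shofactor",
                      mustWork = TRUE)
  out <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  out$sho <- parse_sho(out$sho)
  out
}
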