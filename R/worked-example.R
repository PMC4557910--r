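#' Bundled worked example: conflicting-trend proteins
#'
#' Peptide- and protein-level log2 ratios (muscle-invasive pT2+ over
#' non-muscle-invasive pTa) for the five proteins whose regulation trend
#' disagrees between the labelled and label-free branches of a bladder
#' cancer tissue comparison. The peptide table carries one row per
#' quantified peptide (lower-case letters mark modified residues, as
#' printed); empty cells are peptides quantified by one method only. The
#' protein table carries the published protein-level ratios and p-values
#' for both methods. For four of the five proteins the reporter-ion
#' protein log2 ratio equals the mean of its peptide log2 ratios at two
#' decimals (see [rollup_peptide_log2_ratios()]); the glycosyltransferase
#' subunit averages to -0.05 against a printed -0.06.
#'
#' @return A data.frame (`peptides`: protein, protein_name, peptide,
#'   itraq_log2, lfq_log2; `proteins`: per-method log2 ratio, p-value and
#'   peptide counts).
#' @export
worked_example_peptides <- function() {
  path <- system.file("extdata", "conflicting_trend_peptides.tsv",
                      package = "quantproteo", mustWork = TRUE)
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                    na.strings = c("NA", ""), quote = "", fill = TRUE)
}

#' @rdname worked_example_peptides
#' @export
worked_example_proteins <- function() {
  path <- system.file("extdata", "conflicting_trend_proteins.tsv",
                      package = "quantproteo", mustWork = TRUE)
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                    na.strings = c("NA", ""), quote = "", fill = TRUE)
}
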