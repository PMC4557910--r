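#' Default 8-plex reporter channel labels
#'
#' Nominal reporter masses of the 8-plex isobaric label kit. Note the gap at
#' 120: the series runs 113-119 and then 121.
#'
#' @return Character vector of 8 channel labels.
#' @export
itraq_channels <- function() {
  c("113", "114", "115", "116", "117", "118", "119", "121")
}

reporter_cols <- function(channels = itraq_channels()) {
  paste0("reporter_", channels)
}

#' Canonical peptide-group key
#'
#' Peptides are grouped by sequence plus the multiset of modification names:
#' two PSMs carrying the same modifications at different positions collapse
#' into one peptide group, and precursor charge never enters the key.
#'
#' @param sequence Uppercase amino-acid sequences.
#' @param modifications Modification strings in `"pos:name;pos:name"` form
#'   (position 0 denotes the peptide N-terminus); `""` or `NA` means
#'   unmodified.
#' @return Character vector of keys, one per input row.
#' @export
peptide_key <- function(sequence, modifications = "") {
  modifications[is.na(modifications)] <- ""
  canon <- vapply(modifications, function(m) {
    if (!nzchar(m)) return("")
    toks <- strsplit(m, ";", fixed = TRUE)[[1]]
    nms <- vapply(strsplit(toks, ":", fixed = TRUE), function(t) {
      if (length(t) < 2L) stop("malformed modification token: ", paste(t, collapse = ":"))
      paste(t[-1L], collapse = ":")
    }, character(1))
    paste(sort(nms), collapse = ",")
  }, character(1), USE.NAMES = FALSE)
  paste0(toupper(sequence), "|", canon)
}

parse_modifications <- function(m) {
  if (is.na(m) || !nzchar(m)) {
    return(data.frame(position = integer(0), name = character(0)))
  }
  toks <- strsplit(m, ";", fixed = TRUE)[[1]]
  parts <- strsplit(toks, ":", fixed = TRUE)
  data.frame(
    position = vapply(parts, function(t) as.integer(t[1L]), integer(1)),
    name = vapply(parts, function(t) paste(t[-1L], collapse = ":"), character(1)),
    stringsAsFactors = FALSE
  )
}

split_accessions <- function(x) {
  x[is.na(x)] <- ""
  strsplit(x, ";", fixed = TRUE)
}

# full-precision numeric formatting so result tables round-trip losslessly
format_full <- function(x) {
  out <- vapply(x, function(v) {
    if (is.na(v)) "" else sprintf("%.17g", v)
  }, character(1))
  out
}

# accept decimal commas ("-0,25") in otherwise-numeric cells
normalize_decimal <- function(x) {
  sub("^(-?[0-9]+),([0-9]+)$", "\\1.\\2", trimws(x))
}

as_numeric_checked <- function(x, column, lines = NULL) {
  x <- normalize_decimal(as.character(x))
  x[!nzchar(x) | x == "NA"] <- NA_character_
  out <- suppressWarnings(as.numeric(x))
  bad <- which(!is.na(x) & is.na(out))
  if (length(bad)) {
    where <- if (is.null(lines)) bad[1L] else lines[bad[1L]]
    stop(sprintf("unparsable numeric value '%s' in column '%s' (line %d)",
                 x[bad[1L]], column, where), call. = FALSE)
  }
  out
}
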