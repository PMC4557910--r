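#' Read a PSM table
#'
#' Reads one delimited PSM (peptide-spectrum match) table, the export format
#' of a database-search post-processor. The delimiter (tab or comma) is
#' sniffed from the header line. Cells may use decimal commas; internal
#' representation is always dot-decimal. Empty optional cells are preserved
#' as `NA`, never coerced to 0 -- the label-free imputation rules depend on
#' distinguishing "identified but no integrated area" from zero.
#'
#' Required columns (both modes): `run_id`, `spectrum_id`, `precursor_mz`,
#' `retention_time`, `charge`, `sequence`, `modifications`,
#' `delta_mass_ppm`, `xcorr`, `rank`, `q_value`, `candidate_accessions`.
#' LFQ mode additionally requires `precursor_area`; iTRAQ mode requires the
#' eight `reporter_<channel>` columns and `coisolation_pct`.
#'
#' @param path Path to a TSV/CSV file.
#' @param mode `"lfq"` or `"itraq"`.
#' @return A data.frame of PSMs, one row per table row.
#' @export
read_psm_table <- function(path, mode = c("lfq", "itraq")) {
  mode <- match.arg(mode)
  if (!file.exists(path)) stop("PSM table not found: ", path)
  header <- readLines(path, n = 1L)
  sep <- if (lengths(regmatches(header, gregexpr("\t", header))) >=
             lengths(regmatches(header, gregexpr(",", header, fixed = TRUE)))) "\t" else ","
  raw <- utils::read.table(path, sep = sep, header = TRUE, colClasses = "character",
                           check.names = FALSE, quote = "\"", comment.char = "",
                           stringsAsFactors = FALSE)
  base_cols <- c("run_id", "spectrum_id", "precursor_mz", "retention_time",
                 "charge", "sequence", "modifications", "delta_mass_ppm",
                 "xcorr", "rank", "q_value", "candidate_accessions")
  need <- switch(mode,
    lfq = c(base_cols, "precursor_area"),
    itraq = c(base_cols, reporter_cols(), "coisolation_pct"))
  missing_cols <- setdiff(need, names(raw))
  if (length(missing_cols)) {
    stop("PSM table is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  lines <- seq_len(nrow(raw)) + 1L  # header is line 1
  num <- function(col) as_numeric_checked(raw[[col]], col, lines)
  psms <- data.frame(
    run_id = raw$run_id,
    spectrum_id = raw$spectrum_id,
    precursor_mz = num("precursor_mz"),
    retention_time = num("retention_time"),
    charge = as.integer(num("charge")),
    sequence = toupper(trimws(raw$sequence)),
    modifications = ifelse(is.na(raw$modifications), "", raw$modifications),
    delta_mass_ppm = num("delta_mass_ppm"),
    xcorr = num("xcorr"),
    rank = as.integer(num("rank")),
    q_value = num("q_value"),
    candidate_accessions = raw$candidate_accessions,
    stringsAsFactors = FALSE
  )
  if (mode == "lfq") {
    psms$precursor_area <- num("precursor_area")
  } else {
    for (rc in reporter_cols()) psms[[rc]] <- num(rc)
    rep_mat <- as.matrix(psms[reporter_cols()])
    if (anyNA(rep_mat)) {
      stop("iTRAQ PSM table has missing reporter intensities (line ",
           lines[which(rowSums(is.na(rep_mat)) > 0)[1L]], ")", call. = FALSE)
    }
    psms$coisolation_pct <- num("coisolation_pct")
  }
  attr(psms, "mode") <- mode
  psms
}

#' Write a PSM table
#'
#' Inverse of [read_psm_table()]: writes a tab-separated table that reads
#' back with every populated field intact and numerics at full double
#' precision. Absent values are written as empty cells.
#'
#' @param psms PSM data.frame.
#' @param path Output path.
#' @export
write_psm_table <- function(psms, path) {
  out <- psms
  for (col in names(out)) {
    if (is.numeric(out[[col]]) && !is.integer(out[[col]])) {
      out[[col]] <- format_full(out[[col]])
    }
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE, na = "")
  invisible(path)
}

#' Read a protein sequence database from FASTA
#'
#' The token before the first whitespace in each header becomes the
#' accession; the remainder becomes the description.
#'
#' @param path FASTA file.
#' @return A `protein_db` data.frame with columns `accession`,
#'   `description`, `sequence`.
#' @export
read_fasta <- function(path) {
  seqs <- Biostrings::readAAStringSet(path)
  headers <- names(seqs)
  accession <- sub("\\s.*$", "", headers)
  description <- ifelse(grepl("\\s", headers),
                        sub("^\\S+\\s+", "", headers), "")
  if (anyDuplicated(accession)) {
    stop("duplicate accession(s) in FASTA: ",
         paste(unique(accession[duplicated(accession)]), collapse = ", "),
         call. = FALSE)
  }
  sequence <- as.character(seqs)
  if (any(!nzchar(sequence))) {
    stop("empty sequence for accession(s): ",
         paste(accession[!nzchar(sequence)], collapse = ", "), call. = FALSE)
  }
  protein_db(accession, description, sequence)
}

#' Construct a protein database object
#'
#' @param accession,description,sequence Parallel character vectors.
#' @return A `protein_db` data.frame.
#' @export
protein_db <- function(accession, description, sequence) {
  stopifnot(!anyDuplicated(accession), all(nzchar(sequence)))
  db <- data.frame(accession = accession, description = description,
                   sequence = toupper(sequence), stringsAsFactors = FALSE)
  rownames(db) <- db$accession
  class(db) <- c("protein_db", "data.frame")
  db
}

#' Write a protein database as FASTA
#'
#' @param db A `protein_db`.
#' @param path Output path.
#' @export
write_fasta <- function(db, path) {
  seqs <- Biostrings::AAStringSet(db$sequence)
  names(seqs) <- ifelse(nzchar(db$description),
                        paste(db$accession, db$description), db$accession)
  Biostrings::writeXStringSet(seqs, path, width = 70L)
  invisible(path)
}

#' Read a reporter-ion isotope-impurity matrix
#'
#' Expects 8 data rows by 8 columns (tab- or comma-separated, optional
#' header of channel labels). Values may be fractions or percentages; if
#' any column sums above 1.5 the whole matrix is interpreted as
#' percentages and divided by 100. Column j gives the distribution of
#' label j's signal over observed reporter channels, so
#' `observed = M %*% true`.
#'
#' @param path Path to the matrix file.
#' @return An 8x8 numeric matrix with channel dimnames, validated so each
#'   column sums to a value in (0, 1.0001] with the diagonal as column
#'   maximum.
#' @export
read_impurity_matrix <- function(path) {
  all_lines <- readLines(path)
  all_lines <- all_lines[nzchar(trimws(all_lines))]
  first <- all_lines[1L]
  sep <- if (grepl("\t", first)) "\t" else if (grepl(",", first)) "," else ""
  # channel labels are numeric-looking, so detect a header by line count:
  # 9 lines = labelled 8x8, 8 lines = bare 8x8
  has_header <- length(all_lines) > 8L
  raw <- utils::read.table(path, sep = sep, header = has_header,
                           check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(raw)
  if (!is.numeric(m)) stop("impurity matrix contains non-numeric entries", call. = FALSE)
  if (!all(dim(m) == c(8L, 8L))) {
    stop(sprintf("impurity matrix must be 8x8, got %dx%d", nrow(m), ncol(m)),
         call. = FALSE)
  }
  labels <- if (has_header) as.character(colnames(raw)) else itraq_channels()
  dimnames(m) <- list(labels, labels)
  if (max(colSums(m)) > 1.5) m <- m / 100
  validate_impurity_matrix(m)
}

validate_impurity_matrix <- function(m) {
  if (any(m < 0)) stop("impurity matrix has negative entries", call. = FALSE)
  cs <- colSums(m)
  if (any(cs <= 0) || any(cs > 1.0001)) {
    stop("impurity matrix column sums must lie in (0, 1.0001]; got ",
         paste(signif(cs, 5), collapse = ", "), call. = FALSE)
  }
  if (any(diag(m) < apply(m, 2L, max) - 1e-12)) {
    stop("impurity matrix diagonal must be each column's maximum", call. = FALSE)
  }
  if (abs(det(m)) < 1e-12) stop("impurity matrix is singular", call. = FALSE)
  m
}

#' Write an impurity matrix
#' @param m 8x8 impurity matrix (fractions).
#' @param path Output path.
#' @export
write_impurity_matrix <- function(m, path) {
  utils::write.table(format(m, digits = 17), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = colnames(m))
  invisible(path)
}

#' Synthetic default isotope-impurity matrix
#'
#' A stand-in, vendor-style impurity matrix for the 8-plex reporter series
#' (the true per-batch certificate values ship with each reagent kit and
#' are not bundled here). Each label leaks small satellites to reporters
#' one and two nominal masses away; satellites falling on a mass with no
#' reporter (e.g. 120, between 119 and 121) are lost. This matrix is
#' synthetic and intended for simulation and testing.
#'
#' @param diag_purity Fraction of each label's signal at its own reporter.
#' @return 8x8 column-stochastic-or-less impurity matrix.
#' @export
default_impurity_matrix <- function(diag_purity = 0.93) {
  channels <- itraq_channels()
  masses <- as.integer(channels)
  sat <- c("-2" = 0.002, "-1" = 0.025, "1" = 0.035, "2" = 0.006)
  m <- matrix(0, 8L, 8L, dimnames = list(channels, channels))
  for (j in seq_len(8L)) {
    m[j, j] <- diag_purity
    for (d in names(sat)) {
      target <- masses[j] + as.integer(d)
      i <- match(target, masses)
      if (!is.na(i)) m[i, j] <- sat[[d]]
    }
  }
  validate_impurity_matrix(m)
}

#' Construct a study design
#'
#' Maps sample (LFQ) or channel (iTRAQ) labels to exactly two groups and
#' fixes which group is the case (numerator of the fold change).
#'
#' @param mode `"lfq"` or `"itraq"`.
#' @param group_of Named character vector: names are sample/channel labels,
#'   values are group labels.
#' @param case Group label treated as case; default the second unique group.
#' @param channel_order Channel labels in column order (iTRAQ only).
#' @return A `study_design` list.
#' @export
study_design <- function(mode = c("lfq", "itraq"), group_of,
                         case = NULL, channel_order = NULL) {
  mode <- match.arg(mode)
  groups <- unique(unname(group_of))
  if (length(groups) != 2L) stop("study design must have exactly 2 groups", call. = FALSE)
  if (any(table(group_of) == 0L)) stop("both groups must be non-empty", call. = FALSE)
  if (is.null(case)) case <- groups[2L]
  if (!case %in% groups) stop("case group '", case, "' not in design", call. = FALSE)
  if (mode == "itraq") {
    if (is.null(channel_order)) channel_order <- names(group_of)
    if (length(channel_order) != 8L) stop("iTRAQ design needs 8 channels", call. = FALSE)
    if (!setequal(channel_order, names(group_of))) {
      stop("channel_order must match the labelled channels", call. = FALSE)
    }
  }
  structure(list(mode = mode, group_of = group_of,
                 case = case, control = setdiff(groups, case),
                 channel_order = channel_order),
            class = "study_design")
}

#' Samples/channels of one group
#' @param design A `study_design`.
#' @param group Group label.
#' @return Character vector of sample or channel labels.
#' @export
design_samples <- function(design, group) {
  names(design$group_of)[design$group_of == group]
}

#' Default 4 vs 4 designs
#'
#' The shipped defaults mirror the study layout: 4 non-muscle-invasive
#' (pTa, control) vs 4 muscle-invasive (pT2+, case) bladder-tumor samples;
#' for the labelled experiment channels 113-116 carry pTa and 117, 118,
#' 119, 121 carry pT2+.
#'
#' @param mode `"lfq"` or `"itraq"`.
#' @return A `study_design`.
#' @export
default_design <- function(mode = c("lfq", "itraq")) {
  mode <- match.arg(mode)
  if (mode == "lfq") {
    g <- c(pTa_1 = "pTa", pTa_2 = "pTa", pTa_3 = "pTa", pTa_4 = "pTa",
           pT2_1 = "pT2+", pT2_2 = "pT2+", pT2_3 = "pT2+", pT2_4 = "pT2+")
    study_design("lfq", g, case = "pT2+")
  } else {
    g <- stats::setNames(rep(c("pTa", "pT2+"), each = 4L), itraq_channels())
    study_design("itraq", g, case = "pT2+", channel_order = itraq_channels())
  }
}

#' Read / write a study design (YAML)
#' @param path YAML file with fields `mode`, `groups` (label: group map),
#'   optional `case` and `channel_order`.
#' @return A `study_design`.
#' @export
read_study_design <- function(path) {
  y <- yaml::read_yaml(path)
  study_design(mode = y$mode,
               group_of = unlist(y$groups),
               case = y$case,
               channel_order = if (!is.null(y$channel_order)) as.character(y$channel_order))
}

#' @rdname read_study_design
#' @param design A `study_design` to serialize.
#' @export
write_study_design <- function(design, path) {
  yaml::write_yaml(list(mode = design$mode,
                        groups = as.list(design$group_of),
                        case = design$case,
                        channel_order = design$channel_order), path)
  invisible(path)
}

#' Write / read a differential-expression result table
#'
#' Tab-separated with columns `accession`, `n_peptides`, `log2_ratio`,
#' `p_value`, `direction`, `method`; numerics at full precision so the
#' table round-trips losslessly.
#'
#' @param results Data.frame of results (one method label).
#' @param path Output path.
#' @export
write_results <- function(results, path) {
  cols <- c("accession", "n_peptides", "log2_ratio", "p_value", "direction", "method")
  stopifnot(all(cols %in% names(results)))
  if (nrow(results) && length(unique(results$method)) > 1L) {
    stop("results must share one method label", call. = FALSE)
  }
  out <- results[cols]
  out$log2_ratio <- format_full(out$log2_ratio)
  out$p_value <- format_full(out$p_value)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_results
#' @export
read_results <- function(path) {
  raw <- utils::read.table(path, sep = "\t", header = TRUE, colClasses = "character",
                           stringsAsFactors = FALSE)
  data.frame(accession = raw$accession,
             n_peptides = as.integer(raw$n_peptides),
             log2_ratio = as_numeric_checked(raw$log2_ratio, "log2_ratio"),
             p_value = as_numeric_checked(raw$p_value, "p_value"),
             direction = raw$direction,
             method = raw$method,
             stringsAsFactors = FALSE)
}
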