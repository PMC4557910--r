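#' Build reporter-spectrum records from an iTRAQ PSM table
#'
#' Attaches the peptide grouping key (sequence + modification multiset;
#' charge deliberately ignored) to each spectrum and extracts the 8
#' reporter intensities.
#'
#' @param psms iTRAQ PSM data.frame.
#' @return Data.frame with `spectrum_id`, `sequence`, `modifications`,
#'   `peptide_key`, `coisolation_pct` and one `reporter_<channel>` column
#'   per channel.
#' @export
reporter_spectra <- function(psms) {
  cols <- reporter_cols()
  stopifnot(all(cols %in% names(psms)))
  out <- psms[c("spectrum_id", "sequence", "modifications", "coisolation_pct", cols)]
  out$peptide_key <- peptide_key(psms$sequence, psms$modifications)
  out
}

#' Isotope-impurity correction
#'
#' Unmixes observed reporter intensities by solving
#' `impurity %*% corrected = observed` per spectrum. When the plain linear
#' solve yields negative components the spectrum is re-solved under a
#' non-negativity constraint (non-negative least squares; the default
#' `clamp = "nnls"`), or the negatives are simply truncated to zero
#' (`clamp = "truncate"`). Clamp events are counted in the
#' `n_clamped` attribute.
#'
#' @param x Numeric 8-vector, or a spectra x 8 matrix/data.frame.
#' @param impurity 8x8 impurity matrix (validated, invertible).
#' @param clamp `"nnls"` or `"truncate"`.
#' @return Corrected intensities, same shape as `x`.
#' @export
correct_impurities <- function(x, impurity, clamp = c("nnls", "truncate")) {
  clamp <- match.arg(clamp)
  vec <- is.null(dim(x))
  m <- if (vec) matrix(as.numeric(x), nrow = 1L) else as.matrix(x)
  stopifnot(ncol(m) == 8L, all(dim(impurity) == c(8L, 8L)))
  if (abs(det(impurity)) < 1e-12) stop("impurity matrix is singular", call. = FALSE)
  corrected <- t(solve(impurity, t(m)))
  neg <- which(apply(corrected, 1L, function(r) any(r < -1e-12)))
  for (i in neg) {
    corrected[i, ] <- if (clamp == "nnls") {
      pracma::lsqnonneg(impurity, as.numeric(m[i, ]))$x
    } else {
      pmax(corrected[i, ], 0)
    }
  }
  corrected[corrected < 0 & corrected > -1e-12] <- 0
  if (vec) {
    out <- corrected[1L, ]
    names(out) <- names(x)
  } else {
    out <- corrected
    dimnames(out) <- dimnames(as.matrix(x))
  }
  attr(out, "n_clamped") <- length(neg)
  out
}

# apply impurity correction to the reporter columns of a spectra table
correct_spectra <- function(spectra, impurity, clamp = "nnls") {
  cols <- reporter_cols()
  corrected <- correct_impurities(as.matrix(spectra[cols]), impurity, clamp)
  spectra[cols] <- corrected
  attr(spectra, "n_clamped") <- attr(corrected, "n_clamped")
  spectra
}

#' Zero-reporter substitution
#'
#' A reporter intensity of exactly 0 means the mass tag was not observed in
#' the quantification spectrum. Each zero cell is replaced by the minimal
#' reported (nonzero) intensity -- by default the global minimum over the
#' whole run, or per spectrum with `scope = "spectrum"`. Spectra with all
#' 8 reporters zero carry no quantitative information and are dropped with
#' a warning.
#'
#' @param spectra Reporter-spectra data.frame.
#' @param scope `"run"` (default) or `"spectrum"`.
#' @return Spectra data.frame without zero reporter cells.
#' @export
substitute_zero_reporters <- function(spectra, scope = c("run", "spectrum")) {
  scope <- match.arg(scope)
  cols <- reporter_cols()
  m <- as.matrix(spectra[cols])
  all_zero <- rowSums(m > 0) == 0L
  if (all(all_zero)) stop("every reporter intensity in the run is zero", call. = FALSE)
  if (any(all_zero)) {
    warning(sum(all_zero), " spectrum(s) with all-zero reporters dropped")
    spectra <- spectra[!all_zero, , drop = FALSE]
    m <- m[!all_zero, , drop = FALSE]
  }
  if (scope == "run") {
    floor_val <- min(m[m > 0])
    m[m == 0] <- floor_val
  } else {
    for (i in which(rowSums(m == 0) > 0L)) {
      m[i, m[i, ] == 0] <- min(m[i, m[i, ] > 0])
    }
  }
  spectra[cols] <- m
  spectra
}

#' Co-isolation interference filter
#'
#' Retains spectra whose co-isolation interference is strictly below
#' `max_pct` percent. Spectra lacking a co-isolation value are excluded
#' (conservative) and counted in the `n_missing_coisolation` attribute.
#'
#' @param spectra Reporter-spectra data.frame.
#' @param max_pct Cutoff in percent, default 30.
#' @return Filtered spectra data.frame.
#' @export
coisolation_filter <- function(spectra, max_pct = 30) {
  missing <- is.na(spectra$coisolation_pct)
  keep <- !missing & spectra$coisolation_pct < max_pct
  out <- spectra[keep, , drop = FALSE]
  attr(out, "n_missing_coisolation") <- sum(missing)
  out
}

#' Peptide abundance as the per-channel median over spectra
#'
#' Spectra are grouped by peptide key (mass/sequence plus modification
#' multiset; charge ignored; different modifications give distinct rows)
#' and each channel's abundance is the median over the matching spectra --
#' the median being more outlier-resistant than the mean.
#'
#' @param spectra Corrected, substituted, filtered spectra.
#' @return Peptide x channel numeric matrix (rows named by peptide key),
#'   with a `peptide_info` attribute mapping keys to sequences.
#' @export
peptide_abundance_itraq <- function(spectra) {
  cols <- reporter_cols()
  keys <- sort(unique(spectra$peptide_key))
  out <- matrix(NA_real_, length(keys), 8L,
                dimnames = list(keys, itraq_channels()))
  idx <- split(seq_len(nrow(spectra)), spectra$peptide_key)
  for (k in keys) {
    out[k, ] <- apply(as.matrix(spectra[idx[[k]], cols, drop = FALSE]), 2L,
                      stats::median)
  }
  info <- spectra[match(keys, spectra$peptide_key),
                  c("peptide_key", "sequence", "modifications")]
  rownames(info) <- NULL
  attr(out, "peptide_info") <- info
  out
}

#' Reporter fractions
#'
#' Expresses each peptide's reporter intensities as the ratio of each
#' channel to the sum over all channels, so every row sums to 1.
#'
#' @param tab Peptide x channel matrix of positive abundances.
#' @return Row-normalized matrix.
#' @export
reporter_fractions <- function(tab) {
  rs <- rowSums(tab)
  if (any(rs <= 0)) stop("peptide row(s) with non-positive reporter sum", call. = FALSE)
  tab / rs
}

#' Channel balancing to 12.5%
#'
#' Corrects loading bias by scaling each channel so that its summed
#' quantification share equals 12.5% -- the contribution expected from one
#' of eight labels under equal loading. Since each peptide row of a
#' reporter-fraction table carries one unit of share, the per-channel
#' target is (number of peptides)/8; with that target, balancing is
#' idempotent and exactly undoes any uniform per-channel scaling.
#'
#' @param tab Peptide x channel fraction matrix (rows sum to 1).
#' @return Balanced matrix; every channel total equals 1/8 of the grand
#'   total.
#' @export
balance_channels <- function(tab) {
  stopifnot(nrow(tab) >= 1L)
  totals <- colSums(tab)
  if (any(totals <= 0)) {
    stop("channel(s) with zero total cannot be balanced: ",
         paste(colnames(tab)[totals <= 0], collapse = ", "), call. = FALSE)
  }
  sweep(tab, 2L, (nrow(tab) / 8) / totals, "*")
}

# balanced unique-peptide rows available for one protein
unique_rows <- function(protein_row, mat) {
  intersect(protein_row$unique_peptides[[1L]], rownames(mat))
}

#' Protein quantification, analysis 1 (averaged abundances)
#'
#' For each protein, per-channel abundance is the mean of the balanced
#' quantification values of its unique peptides (shared peptides are never
#' used). The log2 ratio is log2(mean over case channels) - log2(mean over
#' control channels) and the p-value comes from a two-sided
#' independent-samples t-test on the per-channel log2 protein abundances.
#' Proteins with no quantifiable unique peptide are omitted and counted in
#' the `unquantified` attribute.
#'
#' @param mat Balanced peptide x channel matrix.
#' @param proteins A `protein_groups` data.frame.
#' @param design An iTRAQ `study_design`.
#' @param var_equal Pooled-variance Student t (default) or Welch.
#' @param alpha Significance level, default 0.05.
#' @return Result data.frame as in [lfq_differential()], method
#'   `"itraq_a1"`; attribute `unquantified` lists omitted accessions.
#' @export
protein_quant_analysis1 <- function(mat, proteins, design, var_equal = TRUE,
                                    alpha = 0.05) {
  case_ch <- design_samples(design, design$case)
  ctrl_ch <- design_samples(design, design$control)
  res <- list(); skipped <- character(0)
  for (i in seq_len(nrow(proteins))) {
    keys <- unique_rows(proteins[i, ], mat)
    if (!length(keys)) { skipped <- c(skipped, proteins$accession[i]); next }
    ab <- colMeans(mat[keys, , drop = FALSE])
    ratio <- log2(mean(ab[case_ch])) - log2(mean(ab[ctrl_ch]))
    p <- log2_group_ttest(log2(ab[case_ch]), log2(ab[ctrl_ch]), var_equal)
    res[[length(res) + 1L]] <- data.frame(
      accession = proteins$accession[i],
      n_peptides = length(keys),
      log2_ratio = ratio, p_value = p, stringsAsFactors = FALSE)
  }
  out <- if (length(res)) do.call(rbind, res) else
    data.frame(accession = character(0), n_peptides = integer(0),
               log2_ratio = numeric(0), p_value = numeric(0))
  out$direction <- ifelse(out$log2_ratio > 0, "up",
                          ifelse(out$log2_ratio < 0, "down", "flat"))
  out$significant <- !is.na(out$p_value) & out$p_value < alpha
  out$method <- "itraq_a1"
  rownames(out) <- NULL
  attr(out, "unquantified") <- skipped
  out
}

#' Protein quantification, analysis 2 (averaged peptide ratios)
#'
#' Each unique peptide's ratio is the mean of its case-channel values over
#' the mean of its control-channel values; the protein ratio is the mean
#' of its peptide ratios, log2-transformed after averaging. The p-value is
#' the two-sided normal-tail probability of the protein's log2 ratio under
#' the empirical mean and standard deviation of all protein log2 ratios
#' (a z-test against the ratio population).
#'
#' @inheritParams protein_quant_analysis1
#' @return Result data.frame, method `"itraq_a2"`; attribute
#'   `unquantified` lists omitted accessions.
#' @export
protein_quant_analysis2 <- function(mat, proteins, design, alpha = 0.05) {
  case_ch <- design_samples(design, design$case)
  ctrl_ch <- design_samples(design, design$control)
  res <- list(); skipped <- character(0)
  for (i in seq_len(nrow(proteins))) {
    keys <- unique_rows(proteins[i, ], mat)
    if (!length(keys)) { skipped <- c(skipped, proteins$accession[i]); next }
    sub <- mat[keys, , drop = FALSE]
    pep_ratio <- rowMeans(sub[, case_ch, drop = FALSE]) /
      rowMeans(sub[, ctrl_ch, drop = FALSE])
    res[[length(res) + 1L]] <- data.frame(
      accession = proteins$accession[i],
      n_peptides = length(keys),
      log2_ratio = log2(mean(pep_ratio)), stringsAsFactors = FALSE)
  }
  out <- if (length(res)) do.call(rbind, res) else
    data.frame(accession = character(0), n_peptides = integer(0),
               log2_ratio = numeric(0))
  mu <- mean(out$log2_ratio); sdv <- stats::sd(out$log2_ratio)
  out$p_value <- if (nrow(out) >= 2L && !is.na(sdv) && sdv > 0) {
    2 * stats::pnorm(-abs((out$log2_ratio - mu) / sdv))
  } else NA_real_
  out$direction <- ifelse(out$log2_ratio > 0, "up",
                          ifelse(out$log2_ratio < 0, "down", "flat"))
  out$significant <- !is.na(out$p_value) & out$p_value < alpha
  out$method <- "itraq_a2"
  rownames(out) <- NULL
  attr(out, "unquantified") <- skipped
  out
}

#' Protein log2 ratio as the mean of peptide-level log2 ratios
#'
#' Alternative rollup used for worked examples printed at the peptide
#' level: averages already-log2-transformed peptide ratios within each
#' protein. Note this differs from analysis 2, which averages raw ratios
#' and takes the log afterwards.
#'
#' @param peptide_log2 Numeric vector of peptide log2 ratios.
#' @param accession Parallel vector of protein accessions.
#' @return Named numeric vector of per-protein mean log2 ratios.
#' @export
rollup_peptide_log2_ratios <- function(peptide_log2, accession) {
  tapply(peptide_log2, accession, function(x) mean(x[!is.na(x)]))
}

#' Labeling efficiency
#'
#' Percentage of peptides whose N-terminus carries the isobaric label and
#' percentage of lysine-containing peptides with a labeled lysine,
#' computed over unique peptide groups.
#'
#' @param psms iTRAQ PSM data.frame whose `modifications` include label
#'   annotations.
#' @param label_pattern Case-insensitive regex identifying the label
#'   modification name, default `"itraq"`.
#' @return List with `pct_nterm_labeled` and `pct_k_labeled` (percent;
#'   `NA` when the denominator is empty).
#' @export
labeling_efficiency <- function(psms, label_pattern = "itraq") {
  if (!nrow(psms)) return(list(pct_nterm_labeled = NA_real_, pct_k_labeled = NA_real_))
  keys <- peptide_key(psms$sequence, psms$modifications)
  first <- !duplicated(keys)
  seqs <- psms$sequence[first]
  mods <- lapply(psms$modifications[first], parse_modifications)
  is_label <- function(df) grepl(label_pattern, df$name, ignore.case = TRUE)
  nterm <- vapply(mods, function(df) any(is_label(df) & df$position == 0L), logical(1))
  has_k <- grepl("K", seqs, fixed = TRUE)
  k_lab <- mapply(function(df, s) {
    if (!nrow(df)) return(FALSE)
    lab <- is_label(df) & df$position > 0L
    any(lab & substring(s, df$position, df$position) == "K")
  }, mods, seqs)
  list(
    pct_nterm_labeled = 100 * mean(nterm),
    pct_k_labeled = if (any(has_k)) 100 * mean(k_lab[has_k]) else NA_real_
  )
}
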