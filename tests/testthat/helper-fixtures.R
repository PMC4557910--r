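# in-code fixture builders shared across the suite

make_psms <- function(n = 1L, mode = "lfq",
                      run_id = "run1", sequence = "ELVISK",
                      modifications = "", precursor_mz = 500,
                      retention_time = 50, charge = 2L,
                      delta_mass_ppm = 1, xcorr = 3, rank = 1L,
                      q_value = 0.001, candidate_accessions = "P1",
                      precursor_area = 1000, reporters = rep(100, 8),
                      coisolation_pct = 10) {
  df <- data.frame(
    run_id = rep_len(run_id, n),
    spectrum_id = sprintf("s%03d", seq_len(n)),
    precursor_mz = rep_len(precursor_mz, n),
    retention_time = rep_len(retention_time, n),
    charge = rep_len(charge, n),
    sequence = rep_len(sequence, n),
    modifications = rep_len(modifications, n),
    delta_mass_ppm = rep_len(delta_mass_ppm, n),
    xcorr = rep_len(xcorr, n),
    rank = rep_len(rank, n),
    q_value = rep_len(q_value, n),
    candidate_accessions = rep_len(candidate_accessions, n),
    stringsAsFactors = FALSE)
  if (mode == "lfq") {
    df$precursor_area <- rep_len(precursor_area, n)
  } else {
    rep_mat <- matrix(rep(reporters, length.out = 8 * n), n, 8, byrow = TRUE)
    colnames(rep_mat) <- paste0("reporter_", itraq_channels())
    df <- cbind(df, as.data.frame(rep_mat))
    df$coisolation_pct <- rep_len(coisolation_pct, n)
  }
  df
}

make_spectra <- function(intensities, sequence = NULL, coisolation_pct = 10) {
  n <- nrow(intensities)
  if (is.null(sequence)) sequence <- sprintf("PEPTIDE%dK", seq_len(n))
  df <- data.frame(spectrum_id = sprintf("sp%03d", seq_len(n)),
                   sequence = sequence, modifications = "",
                   coisolation_pct = rep_len(coisolation_pct, n),
                   stringsAsFactors = FALSE)
  colnames(intensities) <- paste0("reporter_", itraq_channels())
  df <- cbind(df, as.data.frame(intensities))
  df$peptide_key <- peptide_key(df$sequence, df$modifications)
  df
}

make_db <- function(...) {
  entries <- list(...)
  protein_db(accession = names(entries),
             description = vapply(entries, function(e) e$desc %||% "", character(1)),
             sequence = vapply(entries, function(e) e$seq, character(1)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# peptide_groups built directly from per-sample observation/area vectors
make_peptide_groups <- function(peptides, samples) {
  observed <- do.call(rbind, lapply(peptides, function(p) rep_len(p$observed, length(samples))))
  area <- do.call(rbind, lapply(peptides, function(p) rep_len(p$area %||% NA_real_, length(samples))))
  keys <- vapply(peptides, function(p) peptide_key(p$sequence, p$mods %||% ""), character(1))
  dimnames(observed) <- dimnames(area) <- list(keys, samples)
  pep_df <- data.frame(
    key = keys,
    sequence = vapply(peptides, function(p) p$sequence, character(1)),
    modifications = vapply(peptides, function(p) p$mods %||% "", character(1)),
    candidate_accessions = vapply(peptides, function(p) p$acc, character(1)),
    stringsAsFactors = FALSE)
  structure(list(peptides = pep_df, observed = observed, area = area),
            class = "peptide_groups")
}

# exhaustive minimum set cover oracle (instances with <= 12 proteins)
brute_force_min_cover <- function(cand) {
  prots <- sort(unique(unlist(cand)))
  stopifnot(length(prots) <= 12L)
  best <- length(prots)
  for (size in seq_len(length(prots))) {
    combos <- utils::combn(prots, size, simplify = FALSE)
    for (cb in combos) {
      if (all(vapply(cand, function(a) any(a %in% cb), logical(1)))) {
        return(size)
      }
    }
  }
  best
}

lfq_design_4v4 <- function() default_design("lfq")
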