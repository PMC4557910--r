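AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M", "N",
          "P", "Q", "R", "S", "T", "V", "W", "Y")

rand_tryptic_peptide <- function(min_len = 7L, max_len = 20L, existing = character(0)) {
  interior <- setdiff(AA20, c("K", "R"))
  repeat {
    len <- sample(min_len:max_len, 1L)
    pep <- paste0(paste(sample(interior, len - 1L, replace = TRUE), collapse = ""),
                  sample(c("K", "R"), 1L))
    if (!pep %in% existing) return(pep)
  }
}

#' Generate a ground-truthed synthetic study
#'
#' Builds a two-group proteome with known per-protein log2 fold changes,
#' tryptic-like peptides (random sequences over the 20-letter alphabet,
#' ending in K/R, substrings of their 200-600 residue parents), optional
#' peptides shared between two parents (to exercise parsimony inference
#' and the unique-peptide rule) and optional keratin contaminants (to
#' exercise contaminant exclusion). Deterministic given `seed`.
#'
#' Differential proteins are created in +e/-e pairs with equal peptide
#' counts and pairwise-matched base areas (the down partner's areas are
#' the up partner's times 2^e). This keeps total signal identical between
#' groups, so compositional normalizations (ppm scaling, channel
#' balancing) introduce no group-level bias and noiseless simulations
#' recover every fold change exactly. Shared peptides are placed only on
#' non-differential proteins for the same reason.
#'
#' @param n_proteins Total protein count (including keratin contaminants).
#' @param peptides_per_protein Length-2 range of peptides per protein.
#' @param frac_differential Fraction of non-contaminant proteins with a
#'   nonzero fold change (rounded down to an even count for pairing).
#' @param effect_range Range of true log2 fold changes; magnitudes are
#'   drawn uniformly on (0, max(abs(effect_range))] and signed in pairs.
#' @param frac_shared Fraction of non-differential peptides shared with a
#'   second (non-differential) parent protein.
#' @param frac_keratin Fraction of proteins that are keratin contaminants.
#' @param base_area_meanlog,base_area_sdlog Log-normal parameters of
#'   peptide base abundances.
#' @param seed Integer RNG seed.
#' @return A `synthetic_truth` list: `proteins` (accession, description,
#'   sequence, true_log2_fc, is_keratin, n_peptides), `peptides`
#'   (sequence, protein, accessions, base_area), `seed`, `params`.
#' @export
generate_truth <- function(n_proteins = 100L,
                           peptides_per_protein = c(2L, 8L),
                           frac_differential = 0.3,
                           effect_range = c(-2, 2),
                           frac_shared = 0,
                           frac_keratin = 0,
                           base_area_meanlog = log(1e6),
                           base_area_sdlog = 1,
                           seed = 1L) {
  stopifnot(n_proteins >= 2L, peptides_per_protein[1L] >= 1L,
            frac_differential >= 0, frac_differential <= 1,
            frac_shared >= 0, frac_shared < 1,
            frac_keratin >= 0, frac_keratin < 1)
  set.seed(seed)
  n_keratin <- round(frac_keratin * n_proteins)
  n_core <- n_proteins - n_keratin
  if (n_core < 2L) stop("too few non-contaminant proteins", call. = FALSE)
  n_diff <- 2L * floor(frac_differential * n_core / 2L)
  if (frac_differential > 0 && n_diff == 0L) {
    stop("frac_differential too small to form one +/- pair", call. = FALSE)
  }

  acc <- c(sprintf("SYNP%04d", seq_len(n_core)),
           if (n_keratin) sprintf("SYNK%04d", seq_len(n_keratin)))
  desc <- c(sprintf("synthetic protein %d", seq_len(n_core)),
            if (n_keratin) sprintf("Keratin, type II cytoskeletal %d (synthetic contaminant)",
                                   seq_len(n_keratin)))
  is_keratin <- c(rep(FALSE, n_core), rep(TRUE, n_keratin))

  fc <- numeric(n_proteins)
  if (n_diff > 0L) {
    mag <- stats::runif(n_diff / 2L, 0, max(abs(effect_range)))
    fc[seq_len(n_diff)] <- as.numeric(rbind(mag, -mag))
  }

  n_pep <- sample(peptides_per_protein[1L]:peptides_per_protein[2L],
                  n_proteins, replace = TRUE)
  if (n_diff > 0L) {  # pairs share a peptide count (and pairwise areas below)
    for (i in seq(1L, n_diff, by = 2L)) n_pep[i + 1L] <- n_pep[i]
  }

  all_peps <- character(0)
  pep_rows <- vector("list", n_proteins)
  for (i in seq_len(n_proteins)) {
    seqs <- character(n_pep[i])
    for (j in seq_len(n_pep[i])) {
      seqs[j] <- rand_tryptic_peptide(existing = c(all_peps, seqs))
    }
    all_peps <- c(all_peps, seqs)
    base <- stats::rlnorm(n_pep[i], base_area_meanlog, base_area_sdlog)
    pep_rows[[i]] <- data.frame(sequence = seqs, protein = acc[i],
                                base_area = base, stringsAsFactors = FALSE)
  }
  if (n_diff > 0L) {  # down partner mirrors the up partner's areas times 2^e
    for (i in seq(1L, n_diff, by = 2L)) {
      pep_rows[[i + 1L]]$base_area <- pep_rows[[i]]$base_area * 2^fc[i]
    }
  }
  peptides <- do.call(rbind, pep_rows)
  peptides$accessions <- peptides$protein

  # shared peptides: second parent drawn among other non-differential proteins
  nondiff_prot <- acc[seq_len(n_core)][fc[seq_len(n_core)] == 0 & !is_keratin[seq_len(n_core)]]
  if (frac_shared > 0 && length(nondiff_prot) >= 2L) {
    eligible <- which(peptides$protein %in% nondiff_prot)
    n_share <- round(frac_shared * length(eligible))
    shared_idx <- if (n_share > 0L) sample(eligible, n_share) else integer(0)
    for (s in shared_idx) {
      second <- sample(setdiff(nondiff_prot, peptides$protein[s]), 1L)
      peptides$accessions[s] <- paste(sort(c(peptides$protein[s], second)),
                                      collapse = ";")
    }
  }

  sequences <- character(n_proteins)
  target_len <- sample(200:600, n_proteins, replace = TRUE)
  for (i in seq_len(n_proteins)) {
    own <- peptides$sequence[peptides$protein == acc[i]]
    extra <- peptides$sequence[grepl(paste0("(^|;)", acc[i], "(;|$)"), peptides$accessions) &
                                 peptides$protein != acc[i]]
    body <- paste(c(own, extra), collapse = "")
    filler <- character(0)
    while (nchar(body) + sum(nchar(filler)) < target_len[i]) {
      filler <- c(filler, rand_tryptic_peptide(existing = all_peps))
    }
    sequences[i] <- paste0(body, paste(filler, collapse = ""))
  }

  proteins <- data.frame(accession = acc, description = desc,
                         sequence = sequences, true_log2_fc = fc,
                         is_keratin = is_keratin, n_peptides = n_pep,
                         stringsAsFactors = FALSE)
  structure(list(proteins = proteins, peptides = peptides, seed = seed,
                 params = list(n_proteins = n_proteins,
                               peptides_per_protein = peptides_per_protein,
                               frac_differential = frac_differential,
                               effect_range = effect_range,
                               frac_shared = frac_shared,
                               frac_keratin = frac_keratin)),
            class = "synthetic_truth")
}

#' Protein database of a synthetic truth
#' @param truth A `synthetic_truth`.
#' @return A `protein_db`.
#' @export
truth_db <- function(truth) {
  with(truth$proteins, protein_db(accession, description, sequence))
}

true_fc_of <- function(truth) {
  stats::setNames(truth$proteins$true_log2_fc, truth$proteins$accession)
}

#' Simulate a label-free experiment
#'
#' Emits one PSM table covering `2 * n_per_group` runs (one sample per
#' run). Case-sample peptide areas are `base * 2^fc` times multiplicative
#' log-normal noise (`2^rnorm(sd)` on the log2 scale). Two distinct
#' missingness mechanisms are injected: identified-but-unintegrated PSMs
#' (area absent, row present) at rate `p_unintegrated`, and not-identified
#' peptides (row absent) at rate `p_unidentified`. Each peptide keeps a
#' fixed precursor m/z (grid-spaced so distinct peptides never fall within
#' clustering tolerance) and retention time across runs, with small
#' jitter. Junk PSMs violating exactly one identification filter each are
#' appended at rate `frac_filter_violations`.
#'
#' @param truth A `synthetic_truth`.
#' @param n_per_group Samples per group, default 4.
#' @param noise_sd_log2 SD of log2-scale multiplicative noise.
#' @param p_unintegrated,p_unidentified Missingness rates.
#' @param frac_filter_violations Fraction of extra filter-violating rows.
#' @param seed Integer RNG seed.
#' @return List with `psms` (LFQ PSM data.frame) and `design`.
#' @export
simulate_lfq <- function(truth, n_per_group = 4L, noise_sd_log2 = 0.5,
                         p_unintegrated = 0.05, p_unidentified = 0.05,
                         frac_filter_violations = 0, seed = 1L) {
  set.seed(seed)
  samples <- c(paste0("pTa_", seq_len(n_per_group)),
               paste0("pT2_", seq_len(n_per_group)))
  group_of <- stats::setNames(rep(c("pTa", "pT2+"), each = n_per_group), samples)
  design <- study_design("lfq", group_of, case = "pT2+")
  fc <- true_fc_of(truth)
  peps <- truth$peptides
  np <- nrow(peps)
  mz0 <- 400 + (seq_len(np) - 1L) * 0.05
  rt0 <- stats::runif(np, 10, 200)

  rows <- list()
  sid <- 0L
  for (s in samples) {
    is_case <- group_of[[s]] == "pT2+"
    identified <- stats::runif(np) >= p_unidentified
    idx <- which(identified)
    if (!length(idx)) next
    pep_fc <- fc[peps$protein[idx]]
    area <- peps$base_area[idx] * 2^(pep_fc * is_case) *
      2^stats::rnorm(length(idx), 0, noise_sd_log2)
    area[stats::runif(length(idx)) < p_unintegrated] <- NA_real_
    sid <- sid + length(idx)
    rows[[s]] <- data.frame(
      run_id = s,
      spectrum_id = sprintf("%s_scan%05d", s, seq_along(idx)),
      precursor_mz = mz0[idx] * (1 + stats::rnorm(length(idx), 0, 2e-7)),
      retention_time = rt0[idx] + stats::rnorm(length(idx), 0, 0.05),
      charge = 2L,
      sequence = peps$sequence[idx],
      modifications = "",
      delta_mass_ppm = stats::runif(length(idx), -4.5, 4.5),
      xcorr = stats::runif(length(idx), 2, 5),
      rank = 1L,
      q_value = stats::runif(length(idx), 0, 0.009),
      candidate_accessions = peps$accessions[idx],
      precursor_area = area,
      stringsAsFactors = FALSE)
  }
  psms <- do.call(rbind, rows)
  rownames(psms) <- NULL
  if (frac_filter_violations > 0) {
    psms <- rbind(psms, junk_psms(round(frac_filter_violations * nrow(psms)),
                                  mode = "lfq", accession = peps$protein[1L]))
  }
  attr(psms, "mode") <- "lfq"
  list(psms = psms, design = design)
}

# PSMs each violating exactly one identification filter
junk_psms <- function(n, mode, accession) {
  if (n == 0L) return(NULL)
  kinds <- rep(c("ppm", "q", "rank", "x"), length.out = n)
  seqs <- vapply(seq_len(n), function(i) rand_tryptic_peptide(), character(1))
  df <- data.frame(
    run_id = "junk", spectrum_id = sprintf("junk%04d", seq_len(n)),
    precursor_mz = stats::runif(n, 400, 1200),
    retention_time = stats::runif(n, 10, 200),
    charge = 2L, sequence = seqs, modifications = "",
    delta_mass_ppm = stats::runif(n, -4.5, 4.5),
    xcorr = stats::runif(n, 2, 5), rank = 1L,
    q_value = stats::runif(n, 0, 0.009),
    candidate_accessions = accession, stringsAsFactors = FALSE)
  df$delta_mass_ppm[kinds == "ppm"] <- stats::runif(sum(kinds == "ppm"), 6, 20)
  df$q_value[kinds == "q"] <- stats::runif(sum(kinds == "q"), 0.02, 0.2)
  df$rank[kinds == "rank"] <- sample(6:10, sum(kinds == "rank"), replace = TRUE)
  df$sequence[kinds == "x"] <- paste0(df$sequence[kinds == "x"], "XK")
  if (mode == "lfq") df$precursor_area <- stats::runif(n, 1e4, 1e6)
  df
}

#' Simulate an 8-plex reporter-ion experiment
#'
#' Emits one multi-channel PSM table. True per-channel intensities are
#' `base * 2^fc` for case channels times independent log-normal noise per
#' spectrum and channel, forward-mixed through the impurity matrix before
#' output. Co-isolation percentages are drawn from a Beta distribution
#' scaled to [0, 100]; zero reporters are injected at rate
#' `p_zero_reporter`; each peptide yields several spectra (exercising the
#' median rule). All peptides carry the isobaric label on the N-terminus
#' and on every lysine.
#'
#' @param truth A `synthetic_truth`.
#' @param impurity 8x8 impurity matrix, or `NULL` for identity mixing.
#' @param noise_sd_log2 SD of log2-scale multiplicative noise.
#' @param p_zero_reporter Per-cell zero-injection rate (post-mixing).
#' @param coisolation_beta Beta shape parameters for co-isolation %.
#' @param spectra_per_peptide Length-2 range of spectra per peptide.
#' @param frac_filter_violations Fraction of extra filter-violating rows.
#' @param seed Integer RNG seed.
#' @return List with `psms` (iTRAQ PSM data.frame), `design`, `impurity`.
#' @export
simulate_itraq <- function(truth, impurity = NULL, noise_sd_log2 = 0.3,
                           p_zero_reporter = 0.01,
                           coisolation_beta = c(2, 8),
                           spectra_per_peptide = c(1L, 3L),
                           frac_filter_violations = 0, seed = 1L) {
  set.seed(seed)
  design <- default_design("itraq")
  channels <- design$channel_order
  is_case <- design$group_of[channels] == design$case
  mix <- if (is.null(impurity)) diag(8L) else validate_impurity_matrix(impurity)
  fc <- true_fc_of(truth)
  peps <- truth$peptides

  np <- nrow(peps)
  mods <- vapply(peps$sequence, function(s) {
    k_pos <- which(strsplit(s, "")[[1L]] == "K")
    paste(c("0:iTRAQ8plex",
            if (length(k_pos)) paste0(k_pos, ":iTRAQ8plex")),
          collapse = ";")
  }, character(1), USE.NAMES = FALSE)
  n_spec <- sample(spectra_per_peptide[1L]:spectra_per_peptide[2L], np,
                   replace = TRUE)
  idx <- rep(seq_len(np), n_spec)          # spectrum row -> peptide index
  ns <- length(idx)
  e <- unname(fc[peps$protein[idx]])
  true_int <- (peps$base_area[idx] *
                 matrix(2^stats::rnorm(ns * 8L, 0, noise_sd_log2), ns, 8L)) *
    2^(e %o% as.numeric(is_case))
  obs <- true_int %*% t(mix)               # obs_c = sum_j mix[c, j] * true_j
  obs[matrix(stats::runif(ns * 8L) < p_zero_reporter, ns, 8L)] <- 0
  psms <- data.frame(
    run_id = "itraq_run",
    spectrum_id = sprintf("it_scan%06d", seq_len(ns)),
    precursor_mz = 400 + idx * 0.05,
    retention_time = stats::runif(ns, 10, 200),
    charge = sample(2:3, ns, replace = TRUE),
    sequence = peps$sequence[idx],
    modifications = mods[idx],
    delta_mass_ppm = stats::runif(ns, -4.5, 4.5),
    xcorr = stats::runif(ns, 2, 5),
    rank = 1L,
    q_value = stats::runif(ns, 0, 0.009),
    candidate_accessions = peps$accessions[idx],
    stringsAsFactors = FALSE)
  colnames(obs) <- reporter_cols()
  psms <- cbind(psms, as.data.frame(obs))
  psms$coisolation_pct <- 100 * stats::rbeta(ns, coisolation_beta[1L],
                                             coisolation_beta[2L])
  rownames(psms) <- NULL
  if (frac_filter_violations > 0) {
    junk <- junk_psms(round(frac_filter_violations * nrow(psms)),
                      mode = "itraq", accession = peps$protein[1L])
    junk[reporter_cols()] <- as.list(stats::runif(8L, 100, 1000))
    junk$coisolation_pct <- 10
    psms <- rbind(psms, junk)
  }
  attr(psms, "mode") <- "itraq"
  list(psms = psms, design = design, impurity = mix)
}

#' Write a simulated dataset in the package's file formats
#'
#' Materializes a simulation as the exact artifacts the readers consume:
#' a PSM TSV, a FASTA database, a YAML study design and (for the labelled
#' branch) the impurity matrix TSV.
#'
#' @param sim Output of [simulate_lfq()] or [simulate_itraq()].
#' @param truth The `synthetic_truth` the simulation came from.
#' @param dir Output directory (created if missing).
#' @return Named list of written paths.
#' @export
write_simulation <- function(sim, truth, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(
    psms = file.path(dir, "psms.tsv"),
    fasta = file.path(dir, "proteins.fasta"),
    design = file.path(dir, "design.yaml"))
  write_psm_table(sim$psms, paths$psms)
  write_fasta(truth_db(truth), paths$fasta)
  write_study_design(sim$design, paths$design)
  if (!is.null(sim$impurity)) {
    paths$impurity <- file.path(dir, "impurity.tsv")
    write_impurity_matrix(sim$impurity, paths$impurity)
  }
  paths
}
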