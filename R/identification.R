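#' Peptide-level PSM filters
#'
#' Retains PSMs with absolute mass deviation below `max_ppm`, q-value below
#' `max_q`, rank up to `max_rank`, no unknown amino acid (X) in the
#' sequence, and a non-empty candidate accession list. Input order is
#' preserved. Tightening any threshold never enlarges the surviving set.
#'
#' @param psms PSM data.frame from [read_psm_table()].
#' @param max_ppm Mass-deviation cutoff in ppm (strict `<`), default 5.
#' @param max_q q-value (FDR) cutoff (strict `<`), default 0.01.
#' @param max_rank Highest accepted candidate rank (`<=`), default 5.
#' @return Filtered PSM data.frame.
#' @export
filter_psms <- function(psms, max_ppm = 5, max_q = 0.01, max_rank = 5L) {
  stopifnot(max_ppm > 0, max_q > 0, max_rank > 0)
  if (!nrow(psms)) return(psms)
  acc <- split_accessions(psms$candidate_accessions)
  keep <- abs(psms$delta_mass_ppm) < max_ppm &
    psms$q_value < max_q &
    psms$rank <= max_rank &
    !grepl("X", psms$sequence, fixed = TRUE) &
    lengths(acc) > 0L & vapply(acc, function(a) any(nzchar(a)), logical(1))
  keep[is.na(keep)] <- FALSE
  psms[keep, , drop = FALSE]
}

#' Resolve competing sequence interpretations per spectrum
#'
#' In a multi-run label-free experiment the "same" spectrum (same precursor
#' m/z and retention time, within tolerance) can be interpreted as different
#' sequences in different runs. For each such spectrum cluster the sequence
#' identified in the most samples wins; ties go to the interpretation with
#' the higher best XCorr, remaining ties to the lexicographically smallest
#' sequence. PSMs of losing sequences are dropped.
#'
#' @param psms PSM data.frame (LFQ, multiple runs).
#' @param mz_tol_ppm m/z matching tolerance in ppm (default 10).
#' @param rt_tol_min Retention-time matching tolerance in minutes (default 0.5).
#' @return PSM data.frame with one sequence per spectrum cluster.
#' @export
resolve_spectrum_candidates <- function(psms, mz_tol_ppm = 10, rt_tol_min = 0.5) {
  if (nrow(psms) < 2L) return(psms)
  ord <- order(psms$precursor_mz, psms$retention_time)
  cluster <- integer(nrow(psms))
  ref_mz <- ref_rt <- numeric(0)
  nxt <- 0L
  for (i in ord) {
    mz <- psms$precursor_mz[i]; rt <- psms$retention_time[i]
    hit <- 0L
    if (nxt > 0L) {
      cand <- which(abs(ref_mz - mz) / ref_mz * 1e6 <= mz_tol_ppm &
                      abs(ref_rt - rt) <= rt_tol_min)
      if (length(cand)) hit <- cand[1L]
    }
    if (hit == 0L) {
      nxt <- nxt + 1L
      ref_mz[nxt] <- mz; ref_rt[nxt] <- rt
      hit <- nxt
    }
    cluster[i] <- hit
  }
  keep <- logical(nrow(psms))
  for (cl in split(seq_len(nrow(psms)), cluster)) {
    seqs <- psms$sequence[cl]
    if (length(unique(seqs)) == 1L) { keep[cl] <- TRUE; next }
    n_samp <- tapply(psms$run_id[cl], seqs, function(r) length(unique(r)))
    best_x <- tapply(psms$xcorr[cl], seqs, max)
    tab <- data.frame(seq = names(n_samp), n = as.integer(n_samp),
                      x = as.numeric(best_x[names(n_samp)]))
    tab <- tab[order(-tab$n, -tab$x, tab$seq), ]
    keep[cl] <- seqs == tab$seq[1L]
  }
  psms[sort(which(keep)), , drop = FALSE]
}

#' Collapse PSMs into non-redundant peptide groups
#'
#' Groups PSMs by [peptide_key()] (sequence plus modification multiset;
#' charge and modification positions ignored) and records, per sample, the
#' observation flag and the precursor peak area. When a peptide has several
#' PSMs in one sample the largest integrated area is taken; a peptide
#' identified in a sample but with no integrable area in any of its PSMs
#' gets `NA` there (distinct from "not identified", which stays
#' unobserved).
#'
#' @param psms Filtered PSM data.frame.
#' @param design Optional `study_design`; its sample labels define the
#'   matrix columns. Default: the run ids present in the data.
#' @return A `peptide_groups` list with elements `peptides` (data.frame:
#'   `key`, `sequence`, `modifications`, `candidate_accessions`),
#'   `observed` (logical peptide x sample matrix) and `area` (numeric
#'   peptide x sample matrix, `NA` = identified without area).
#' @export
build_peptide_groups <- function(psms, design = NULL) {
  samples <- if (!is.null(design)) names(design$group_of) else unique(psms$run_id)
  key <- peptide_key(psms$sequence, psms$modifications)
  keys <- sort(unique(key))
  observed <- matrix(FALSE, length(keys), length(samples),
                     dimnames = list(keys, samples))
  area <- matrix(NA_real_, length(keys), length(samples),
                 dimnames = list(keys, samples))
  has_area <- "precursor_area" %in% names(psms)
  idx <- split(seq_len(nrow(psms)), key)
  seqs <- mods <- accs <- character(length(keys))
  names(seqs) <- keys
  for (k in keys) {
    rows <- idx[[k]]
    seqs[k] <- psms$sequence[rows[1L]]
    mods[match(k, keys)] <- psms$modifications[rows[1L]]
    accs[match(k, keys)] <- paste(
      sort(unique(unlist(split_accessions(psms$candidate_accessions[rows])))),
      collapse = ";")
    for (r in rows) {
      s <- psms$run_id[r]
      if (!s %in% samples) next
      observed[k, s] <- TRUE
      if (has_area && !is.na(psms$precursor_area[r])) {
        a <- psms$precursor_area[r]
        area[k, s] <- if (is.na(area[k, s])) a else max(area[k, s], a)
      }
    }
  }
  peptides <- data.frame(key = keys, sequence = unname(seqs),
                         modifications = mods,
                         candidate_accessions = accs,
                         stringsAsFactors = FALSE)
  structure(list(peptides = peptides, observed = observed, area = area),
            class = "peptide_groups")
}

subset_peptide_groups <- function(pg, keep) {
  structure(list(peptides = pg$peptides[keep, , drop = FALSE],
                 observed = pg$observed[keep, , drop = FALSE],
                 area = pg$area[keep, , drop = FALSE]),
            class = "peptide_groups")
}

#' Exclude contaminant (keratin) peptides
#'
#' Any peptide whose candidate accession set contains a protein whose
#' description matches the contaminant pattern is removed entirely -- even
#' when it also maps to non-contaminant proteins -- so that contaminant
#' signal can never leak into quantification.
#'
#' @param pg A `peptide_groups` object.
#' @param db A `protein_db`.
#' @param pattern Case-insensitive regex on protein descriptions
#'   (default `"keratin"`).
#' @return Filtered `peptide_groups`.
#' @export
exclude_keratins <- function(pg, db, pattern = "keratin") {
  bad_acc <- db$accession[grepl(pattern, db$description, ignore.case = TRUE)]
  if (!length(bad_acc)) return(pg)
  hit <- vapply(split_accessions(pg$peptides$candidate_accessions),
                function(a) any(a %in% bad_acc), logical(1))
  subset_peptide_groups(pg, !hit)
}

#' Group-consistency filter
#'
#' A peptide is credible only when observed in at least (default) 75% of
#' the samples of at least one group. With 4 samples per group the default
#' admits 3/4; `strict = TRUE` switches to a strictly-greater comparison
#' (4/4 with the default threshold).
#'
#' @param pg A `peptide_groups` object (LFQ).
#' @param design A `study_design`.
#' @param threshold Required observation fraction, default 0.75.
#' @param strict Use `>` instead of `>=`.
#' @return Filtered `peptide_groups`.
#' @export
consistency_filter <- function(pg, design, threshold = 0.75, strict = FALSE) {
  stopifnot(all(names(design$group_of) %in% colnames(pg$observed)))
  groups <- unique(unname(design$group_of))
  frac <- sapply(groups, function(g) {
    cols <- design_samples(design, g)
    rowMeans(pg$observed[, cols, drop = FALSE])
  })
  frac <- matrix(frac, nrow = nrow(pg$observed))
  ok <- if (strict) frac > threshold else frac >= threshold
  subset_peptide_groups(pg, apply(ok, 1L, any))
}

#' Parsimonious (Occam-razor) protein inference
#'
#' Selects a minimal protein set explaining every peptide by greedy set
#' cover (iteratively pick the accession covering the most unexplained
#' peptides; ties broken by accession order), then assigns each shared
#' peptide to exactly one selected protein: the one with more total
#' peptide evidence, ties again by accession order. Selected proteins left
#' without assigned peptides are dropped.
#'
#' @param pg A `peptide_groups` object.
#' @param db A `protein_db`; every candidate accession must resolve here.
#' @return A `protein_groups` data.frame: `accession`, `n_peptides`,
#'   list-columns `peptides` (assigned keys) and `unique_peptides` (keys
#'   matching no other selected protein).
#' @export
infer_proteins_occam <- function(pg, db) {
  cand <- split_accessions(pg$peptides$candidate_accessions)
  names(cand) <- pg$peptides$key
  unresolved <- setdiff(unique(unlist(cand)), db$accession)
  if (length(unresolved)) {
    stop("peptide candidate accession(s) not in database: ",
         paste(unresolved, collapse = ", "), call. = FALSE)
  }
  no_cand <- lengths(cand) == 0L
  if (any(no_cand)) {
    stop("peptide(s) with no resolvable accession: ",
         paste(names(cand)[no_cand], collapse = ", "), call. = FALSE)
  }
  # protein -> peptides it could explain
  prot_peps <- split(rep(names(cand), lengths(cand)), unlist(cand))
  selected <- character(0)
  unexplained <- names(cand)
  while (length(unexplained)) {
    gain <- vapply(prot_peps, function(p) sum(p %in% unexplained), integer(1))
    gain <- gain[gain > 0L]
    pick <- names(gain)[order(-gain, names(gain))][1L]
    selected <- c(selected, pick)
    unexplained <- setdiff(unexplained, prot_peps[[pick]])
  }
  evidence <- vapply(prot_peps[selected], length, integer(1))
  assigned <- vapply(names(cand), function(k) {
    opts <- intersect(cand[[k]], selected)
    opts[order(-evidence[opts], opts)][1L]
  }, character(1))
  groups <- lapply(stats::setNames(selected, selected),
                   function(p) names(assigned)[assigned == p])
  groups <- groups[lengths(groups) > 0L]
  accs <- sort(names(groups))
  uniq <- lapply(accs, function(p) {
    keys <- groups[[p]]
    keys[vapply(keys, function(k) length(intersect(cand[[k]], accs)) == 1L, logical(1))]
  })
  out <- data.frame(accession = accs,
                    n_peptides = lengths(groups[accs]),
                    stringsAsFactors = FALSE)
  out$peptides <- unname(groups[accs])
  out$unique_peptides <- uniq
  class(out) <- c("protein_groups", "data.frame")
  out
}

#' Multiple-peptide rule
#'
#' Keeps proteins identified by at least `min_peptides` peptides (default
#' 2) and reports the number of single-peptide identifications plus the
#' peptides-per-protein histogram of the unfiltered input.
#'
#' @param proteins A `protein_groups` data.frame.
#' @param min_peptides Minimum peptide count, default 2.
#' @return List with `proteins` (retained groups), `n_single`
#'   (single-peptide count) and `histogram` (counts over 1/2/3/>=4).
#' @export
require_min_peptides <- function(proteins, min_peptides = 2L) {
  hist <- peptides_per_protein_histogram(proteins$n_peptides)
  list(proteins = proteins[proteins$n_peptides >= min_peptides, , drop = FALSE],
       n_single = sum(proteins$n_peptides == 1L),
       histogram = hist)
}
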