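#' Identification-set overlap counts
#'
#' Exact Venn region counts for 2 or 3 labelled identifier sets (peptide
#' sequences or protein accessions). Duplicates within a set are removed
#' with a warning. Region counts always sum to the union size and each
#' set's regions sum to its size.
#'
#' @param sets Named list of 2 or 3 character vectors.
#' @return List with `sizes` (per set), `regions` (named by
#'   `&`-joined set labels) and `union_size`.
#' @export
overlap_counts <- function(sets) {
  stopifnot(is.list(sets), length(sets) %in% c(2L, 3L), !is.null(names(sets)))
  dup <- vapply(sets, anyDuplicated, integer(1)) > 0L
  if (any(dup)) {
    warning("duplicate identifiers removed in set(s): ",
            paste(names(sets)[dup], collapse = ", "))
    sets <- lapply(sets, unique)
  }
  universe <- unique(unlist(sets))
  membership <- vapply(sets, function(s) universe %in% s, logical(length(universe)))
  membership <- matrix(membership, ncol = length(sets),
                       dimnames = list(NULL, names(sets)))
  pattern <- apply(membership, 1L, function(r) paste(names(sets)[r], collapse = "&"))
  regions <- table(pattern)
  list(sizes = vapply(sets, length, integer(1)),
       regions = stats::setNames(as.integer(regions), names(regions)),
       union_size = length(universe))
}

#' Protein sequence coverage
#'
#' Percentage of a protein's residues covered by at least one of the given
#' peptides. Every occurrence of a peptide in the sequence is marked as
#' covered and overlapping occurrences are merged (counted once).
#'
#' @param protein_seq Protein amino-acid sequence (length-1 character).
#' @param peptide_seqs Character vector of peptide sequences.
#' @return Coverage in percent (0-100).
#' @export
sequence_coverage <- function(protein_seq, peptide_seqs) {
  n <- nchar(protein_seq)
  if (!length(peptide_seqs)) return(0)
  covered <- logical(n)
  for (p in unique(peptide_seqs)) {
    hits <- gregexpr(p, protein_seq, fixed = TRUE)[[1L]]
    if (hits[1L] == -1L) {
      stop("peptide not found in protein sequence: ", p, call. = FALSE)
    }
    for (h in hits) covered[h:(h + nchar(p) - 1L)] <- TRUE
  }
  100 * sum(covered) / n
}

#' Coverage statistics for inferred protein groups
#'
#' @param proteins A `protein_groups` data.frame (peptide keys carry the
#'   sequence before the `|` separator).
#' @param db A `protein_db`.
#' @return Data.frame with `accession`, `n_peptides`, `coverage_pct`; the
#'   `mean_coverage` and `mean_peptides_per_protein` attributes summarize
#'   the method.
#' @export
protein_coverage <- function(proteins, db) {
  cov <- vapply(seq_len(nrow(proteins)), function(i) {
    acc <- proteins$accession[i]
    peps <- unique(sub("\\|.*$", "", proteins$peptides[[i]]))
    sequence_coverage(db[acc, "sequence"], peps)
  }, numeric(1))
  out <- data.frame(accession = proteins$accession,
                    n_peptides = proteins$n_peptides,
                    coverage_pct = cov, stringsAsFactors = FALSE)
  attr(out, "mean_coverage") <- mean(cov)
  attr(out, "mean_peptides_per_protein") <- mean(proteins$n_peptides)
  out
}

#' Peptides-per-protein histogram
#'
#' Counts proteins identified by exactly 1, 2, 3 and >= 4 peptides.
#'
#' @param n_peptides Integer vector of per-protein peptide counts.
#' @return Named integer vector over bins `1`, `2`, `3`, `>=4`.
#' @export
peptides_per_protein_histogram <- function(n_peptides) {
  c(`1` = sum(n_peptides == 1L),
    `2` = sum(n_peptides == 2L),
    `3` = sum(n_peptides == 3L),
    `>=4` = sum(n_peptides >= 4L))
}

#' Pearson correlation and regression between two ratio vectors
#'
#' @param a,b Paired numeric vectors (>= 3 complete pairs).
#' @return List with `r`, `slope`, `intercept`, `p` (correlation test) and
#'   `n`; all-`NA` flags when either coordinate has zero variance.
#' @export
correlate_ratios <- function(a, b) {
  ok <- stats::complete.cases(a, b)
  a <- a[ok]; b <- b[ok]
  if (length(a) < 3L) stop("need at least 3 complete pairs", call. = FALSE)
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    return(list(r = NA_real_, slope = NA_real_, intercept = NA_real_,
                p = NA_real_, n = length(a)))
  }
  ct <- stats::cor.test(a, b, method = "pearson")
  fit <- stats::coef(stats::lm(b ~ a))
  list(r = unname(ct$estimate), slope = unname(fit[2L]),
       intercept = unname(fit[1L]), p = ct$p.value, n = length(a))
}

#' Regulation-trend concordance between two methods
#'
#' Proteins quantified by both methods and significant in at least one are
#' classified `consistent` (same sign of log2 ratio) or `conflicting`
#' (opposite signs). A ratio of exactly 0 is treated as consistent with
#' either sign and flagged. Proteins significant in one method but absent
#' from the other's table are listed as method-exclusive.
#'
#' @param results_a,results_b Result data.frames (as from the
#'   differential-expression functions), keyed by accession.
#' @param alpha Significance level, default 0.05.
#' @return List with `table` (per shared significant protein:
#'   both ratios, p-values, classification), `n_consistent`,
#'   `n_conflicting`, `exclusive_a`, `exclusive_b` and `shared_signs`
#'   (direction agreement over all shared quantified proteins, significant
#'   or not).
#' @export
trend_concordance <- function(results_a, results_b, alpha = 0.05) {
  m <- merge(results_a, results_b, by = "accession", suffixes = c("_a", "_b"))
  m <- m[!is.na(m$log2_ratio_a) & !is.na(m$log2_ratio_b), , drop = FALSE]
  sig_a <- !is.na(m$p_value_a) & m$p_value_a < alpha
  sig_b <- !is.na(m$p_value_b) & m$p_value_b < alpha
  any_sig <- sig_a | sig_b
  tab <- m[any_sig, c("accession", "log2_ratio_a", "p_value_a",
                      "log2_ratio_b", "p_value_b"), drop = FALSE]
  s <- sign(tab$log2_ratio_a) * sign(tab$log2_ratio_b)
  tab$classification <- ifelse(s < 0, "conflicting", "consistent")
  tab$flat_flag <- sign(tab$log2_ratio_a) == 0 | sign(tab$log2_ratio_b) == 0
  sig_only_a <- results_a$accession[
    !is.na(results_a$p_value) & results_a$p_value < alpha &
      !results_a$accession %in% results_b$accession]
  sig_only_b <- results_b$accession[
    !is.na(results_b$p_value) & results_b$p_value < alpha &
      !results_b$accession %in% results_a$accession]
  rownames(tab) <- NULL
  list(table = tab,
       n_consistent = sum(tab$classification == "consistent"),
       n_conflicting = sum(tab$classification == "conflicting"),
       exclusive_a = sig_only_a,
       exclusive_b = sig_only_b,
       shared_signs = mean(sign(m$log2_ratio_a) == sign(m$log2_ratio_b)))
}

#' Modification prevalence
#'
#' For each modification rule, the denominator is the number of unique
#' peptides containing at least one target site (a residue from `targets`,
#' or any peptide when the target is the N-terminus) and the numerator the
#' number of those actually carrying the modification. Reported as the
#' fraction of modified peptides over peptides that could possibly carry
#' the modification.
#'
#' @param psms PSM data.frame.
#' @param rules Data.frame with columns `name` (modification name as it
#'   appears in the `modifications` field) and `targets` (string of target
#'   residues, e.g. `"M"`; `"nterm"` for protein/peptide N-termini).
#' @return Data.frame with `name`, `n_eligible`, `n_modified`, `fraction`,
#'   `pct` (`NA` when no peptide is eligible).
#' @export
modification_prevalence <- function(psms, rules) {
  keys <- peptide_key(psms$sequence, psms$modifications)
  first <- !duplicated(keys)
  seqs <- psms$sequence[first]
  mods <- lapply(psms$modifications[first], parse_modifications)
  res <- lapply(seq_len(nrow(rules)), function(i) {
    name <- rules$name[i]; targets <- rules$targets[i]
    eligible <- if (identical(tolower(targets), "nterm")) {
      rep(TRUE, length(seqs))
    } else {
      grepl(sprintf("[%s]", targets), seqs)
    }
    carries <- vapply(mods, function(df) name %in% df$name, logical(1))
    n_el <- sum(eligible)
    n_mod <- sum(carries & eligible)
    data.frame(name = name, n_eligible = n_el, n_modified = n_mod,
               fraction = if (n_el > 0L) n_mod / n_el else NA_real_,
               pct = if (n_el > 0L) 100 * n_mod / n_el else NA_real_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}
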