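#' Impute missing peptide areas
#'
#' Two distinct missingness mechanisms are handled differently. A peptide
#' identified in a sample but with no integrable precursor area (`NA` with
#' `observed = TRUE`) receives the mean of that peptide's available areas
#' within the same group; if no group value is available the cell is set to
#' 0 with a warning. A peptide not identified in a sample is set to 0.
#'
#' @param area Peptide x sample numeric matrix (`NA` = identified without
#'   area).
#' @param observed Parallel logical matrix of identification flags.
#' @param design A `study_design` covering the columns.
#' @return Numeric matrix with no `NA` cells.
#' @export
impute_missing_areas <- function(area, observed, design) {
  stopifnot(identical(dim(area), dim(observed)),
            all(colnames(area) %in% names(design$group_of)))
  out <- area
  groups <- unique(unname(design$group_of))
  n_empty <- 0L
  for (g in groups) {
    cols <- intersect(design_samples(design, g), colnames(area))
    sub <- area[, cols, drop = FALSE]
    obs <- observed[, cols, drop = FALSE]
    avail <- !is.na(sub) & obs
    means <- rowSums(ifelse(avail, sub, 0)) / rowSums(avail)
    for (j in seq_along(cols)) {
      fill <- obs[, j] & is.na(sub[, j])
      if (!any(fill)) next
      v <- means[fill]
      empty <- is.na(v) | is.nan(v)
      n_empty <- n_empty + sum(empty)
      v[empty] <- 0
      out[which(fill), cols[j]] <- v
    }
  }
  out[!observed] <- 0
  if (n_empty > 0L) {
    warning(n_empty, " identified-without-area cell(s) had no available ",
            "group values; set to 0")
  }
  out
}

#' Parts-per-million normalization
#'
#' Scales each sample column so that normalized peak areas sum to 10^6:
#' normalized area = (peptide area / total area) x 10^6. Idempotent, and
#' invariant to rescaling any single sample's raw areas.
#'
#' @param mat Peptide x sample matrix of non-negative areas.
#' @return Matrix with every column summing to 10^6.
#' @export
ppm_normalize <- function(mat) {
  totals <- colSums(mat)
  zero <- totals <= 0
  if (any(zero)) {
    stop("sample(s) with all-zero areas cannot be normalized: ",
         paste(colnames(mat)[zero], collapse = ", "), call. = FALSE)
  }
  sweep(mat, 2L, totals, "/") * 1e6
}

#' Protein abundance by summed peptide areas
#'
#' Protein abundance per sample is the sum of the normalized areas of the
#' peptides assigned to that protein. Shared peptides contribute only to
#' the single protein the parsimony assignment selected.
#'
#' @param mat Normalized peptide x sample matrix (rows named by peptide
#'   key).
#' @param proteins A `protein_groups` data.frame.
#' @return Protein x sample abundance matrix.
#' @export
protein_abundance_lfq <- function(mat, proteins) {
  out <- matrix(0, nrow(proteins), ncol(mat),
                dimnames = list(proteins$accession, colnames(mat)))
  for (i in seq_len(nrow(proteins))) {
    keys <- intersect(proteins$peptides[[i]], rownames(mat))
    if (length(keys)) out[i, ] <- colSums(mat[keys, , drop = FALSE])
  }
  out
}

# two-sided two-sample t on log2 values with the degenerate cases pinned:
# all values identical -> p = 1; zero variance in both groups with
# different means -> p undefined (NA)
log2_group_ttest <- function(x_case, x_ctrl, var_equal = TRUE) {
  if (max(c(x_case, x_ctrl)) - min(c(x_case, x_ctrl)) < 1e-12) return(1)
  if (stats::sd(x_case) < 1e-12 && stats::sd(x_ctrl) < 1e-12) return(NA_real_)
  tryCatch(stats::t.test(x_case, x_ctrl, var.equal = var_equal)$p.value,
           error = function(e) NA_real_)
}

#' Label-free differential expression
#'
#' For each protein the group means of the (raw-scale) abundances are log2
#' transformed and subtracted: log2 ratio = log2(mean case) - log2(mean
#' control). The p-value comes from a two-sided independent-samples t-test
#' on per-sample log2 abundances (pooled-variance Student by default;
#' Welch via `var_equal = FALSE`). Zeros are replaced by half the
#' protein's smallest nonzero abundance before the log transform for the
#' test; a protein with a zero group mean gets an undefined ratio and is
#' excluded from significance calls.
#'
#' @param tab Protein x sample abundance matrix.
#' @param design A `study_design` with >= 2 samples per group.
#' @param proteins Optional `protein_groups` (supplies `n_peptides`).
#' @param var_equal Pooled-variance Student t (default) or Welch.
#' @param alpha Significance level, default 0.05.
#' @param adjust Multiple-testing correction passed to [stats::p.adjust()]
#'   for the additional `p_adjusted` column; default `"none"`.
#' @param method_label Method tag stored in the result, default `"lfq"`.
#' @return Data.frame of per-protein results: `accession`, `n_peptides`,
#'   `log2_ratio`, `p_value`, `p_adjusted`, `direction`, `significant`,
#'   `method`. Attribute `n_zero_substituted` counts zero replacements.
#' @export
lfq_differential <- function(tab, design, proteins = NULL, var_equal = TRUE,
                             alpha = 0.05, adjust = "none",
                             method_label = "lfq") {
  case_cols <- design_samples(design, design$case)
  ctrl_cols <- design_samples(design, design$control)
  stopifnot(length(case_cols) >= 2L, length(ctrl_cols) >= 2L,
            all(c(case_cols, ctrl_cols) %in% colnames(tab)))
  n_pep <- if (!is.null(proteins)) {
    stats::setNames(proteins$n_peptides, proteins$accession)[rownames(tab)]
  } else rep(NA_integer_, nrow(tab))
  n_sub <- 0L
  res <- lapply(seq_len(nrow(tab)), function(i) {
    v <- tab[i, ]
    case_mean <- mean(v[case_cols]); ctrl_mean <- mean(v[ctrl_cols])
    ratio <- if (case_mean <= 0 || ctrl_mean <= 0) NA_real_ else
      log2(case_mean) - log2(ctrl_mean)
    if (is.na(ratio)) {
      p <- NA_real_
    } else {
      w <- v[c(case_cols, ctrl_cols)]
      if (any(w == 0)) {
        nz <- w[w > 0]
        w[w == 0] <- min(nz) / 2
        n_sub <<- n_sub + sum(v[c(case_cols, ctrl_cols)] == 0)
      }
      x <- log2(w)
      p <- log2_group_ttest(x[case_cols], x[ctrl_cols], var_equal)
    }
    data.frame(accession = rownames(tab)[i],
               n_peptides = n_pep[i],
               log2_ratio = ratio, p_value = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$p_adjusted <- stats::p.adjust(out$p_value, method = adjust)
  out$direction <- ifelse(is.na(out$log2_ratio), NA_character_,
                          ifelse(out$log2_ratio > 0, "up",
                                 ifelse(out$log2_ratio < 0, "down", "flat")))
  out$significant <- !is.na(out$p_value) & !is.na(out$log2_ratio) &
    out$p_value < alpha
  out$method <- method_label
  rownames(out) <- NULL
  attr(out, "n_zero_substituted") <- n_sub
  out
}
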