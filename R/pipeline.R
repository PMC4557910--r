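#' Default pipeline parameters
#'
#' The shipped defaults are the study thresholds: mass deviation < 5 ppm,
#' FDR < 1%, rank <= 5, group-consistency >= 75%, co-isolation < 30%,
#' >= 2 peptides per protein, alpha = 0.05, 4 vs 4 design.
#'
#' @return Named list of parameters.
#' @export
default_params <- function() {
  list(max_ppm = 5, max_q = 0.01, max_rank = 5L,
       mz_tol_ppm = 10, rt_tol_min = 0.5,
       contaminant_pattern = "keratin",
       consistency_threshold = 0.75, strict_consistency = FALSE,
       min_peptides = 2L,
       coisolation_max = 30, zero_scope = "run", clamp_policy = "nnls",
       ttest_var_equal = TRUE, alpha = 0.05, adjust = "none")
}

merge_params <- function(params) {
  out <- default_params()
  for (k in names(params)) out[[k]] <- params[[k]]
  out
}

#' Run the label-free pipeline
#'
#' PSM filtering, cross-run spectrum resolution, peptide grouping, keratin
#' exclusion, group-consistency filtering, parsimony protein inference,
#' the multiple-peptide rule, missing-area imputation, ppm normalization,
#' sum rollup and differential testing, in that order.
#'
#' @param psms LFQ PSM data.frame (all runs, `run_id` = sample label).
#' @param db A `protein_db`.
#' @param design An LFQ `study_design`.
#' @param params Parameter overrides merged over [default_params()].
#' @return List: `results` (differential-expression table),
#'   `protein_table` (protein x sample abundances), `peptide_matrix`
#'   (normalized peptide x sample), `proteins`, `manifest`.
#' @export
run_lfq_pipeline <- function(psms, db, design, params = list()) {
  p <- merge_params(params)
  filtered <- filter_psms(psms, p$max_ppm, p$max_q, p$max_rank)
  resolved <- resolve_spectrum_candidates(filtered, p$mz_tol_ppm, p$rt_tol_min)
  pg <- build_peptide_groups(resolved, design)
  n_pep0 <- nrow(pg$peptides)
  pg <- exclude_keratins(pg, db, p$contaminant_pattern)
  n_after_keratin <- nrow(pg$peptides)
  pg <- consistency_filter(pg, design, p$consistency_threshold, p$strict_consistency)
  proteins_all <- infer_proteins_occam(pg, db)
  mp <- require_min_peptides(proteins_all, p$min_peptides)
  imputed <- impute_missing_areas(pg$area, pg$observed, design)
  normalized <- ppm_normalize(imputed)
  protein_table <- protein_abundance_lfq(normalized, mp$proteins)
  results <- lfq_differential(protein_table, design, mp$proteins,
                              var_equal = p$ttest_var_equal, alpha = p$alpha,
                              adjust = p$adjust)
  manifest <- list(
    mode = "lfq",
    counts = list(psm_input = nrow(psms), psm_filtered = nrow(filtered),
                  psm_resolved = nrow(resolved),
                  peptides = n_pep0, peptides_after_keratin = n_after_keratin,
                  peptides_consistent = nrow(pg$peptides),
                  proteins = nrow(proteins_all),
                  proteins_single_peptide = mp$n_single,
                  proteins_reported = nrow(mp$proteins)),
    histogram = as.list(mp$histogram),
    params = p)
  list(results = results, protein_table = protein_table,
       peptide_matrix = normalized, proteins = mp$proteins,
       manifest = manifest)
}

#' Run the 8-plex reporter-ion pipeline
#'
#' PSM filtering, peptide grouping, keratin exclusion, parsimony
#' inference, the multiple-peptide rule; then, at spectrum level, isotope
#' impurity correction, zero-reporter substitution and the co-isolation
#' filter; then median peptide abundances, reporter fractions, channel
#' balancing and both protein quantification strategies.
#'
#' @param psms iTRAQ PSM data.frame (single multiplexed run).
#' @param db A `protein_db`.
#' @param design An iTRAQ `study_design`.
#' @param impurity 8x8 impurity matrix or `NULL` for identity.
#' @param params Parameter overrides merged over [default_params()].
#' @return List: `results_analysis1`, `results_analysis2`,
#'   `peptide_matrix` (balanced peptide x channel), `proteins`,
#'   `manifest`.
#' @export
run_itraq_pipeline <- function(psms, db, design, impurity = NULL,
                               params = list()) {
  p <- merge_params(params)
  filtered <- filter_psms(psms, p$max_ppm, p$max_q, p$max_rank)
  pg <- build_peptide_groups(filtered)
  n_pep0 <- nrow(pg$peptides)
  pg <- exclude_keratins(pg, db, p$contaminant_pattern)
  proteins_all <- infer_proteins_occam(pg, db)
  mp <- require_min_peptides(proteins_all, p$min_peptides)

  spectra <- reporter_spectra(filtered)
  spectra <- spectra[spectra$peptide_key %in% pg$peptides$key, , drop = FALSE]
  if (!is.null(impurity)) {
    spectra <- correct_spectra(spectra, impurity, p$clamp_policy)
  }
  n_clamped <- attr(spectra, "n_clamped")
  spectra <- substitute_zero_reporters(spectra, p$zero_scope)
  spectra <- coisolation_filter(spectra, p$coisolation_max)
  n_missing_coiso <- attr(spectra, "n_missing_coisolation")
  pep_ab <- peptide_abundance_itraq(spectra)
  balanced <- balance_channels(reporter_fractions(pep_ab))
  a1 <- protein_quant_analysis1(balanced, mp$proteins, design,
                                var_equal = p$ttest_var_equal, alpha = p$alpha)
  a2 <- protein_quant_analysis2(balanced, mp$proteins, design, alpha = p$alpha)
  manifest <- list(
    mode = "itraq",
    counts = list(psm_input = nrow(psms), psm_filtered = nrow(filtered),
                  peptides = n_pep0, peptides_after_keratin = nrow(pg$peptides),
                  spectra_quantifiable = nrow(spectra),
                  peptides_quantified = nrow(pep_ab),
                  proteins = nrow(proteins_all),
                  proteins_single_peptide = mp$n_single,
                  proteins_reported = nrow(mp$proteins),
                  proteins_unquantified = length(attr(a1, "unquantified")),
                  spectra_clamped = if (is.null(n_clamped)) 0L else n_clamped,
                  spectra_missing_coisolation = n_missing_coiso),
    histogram = as.list(mp$histogram),
    params = p)
  list(results_analysis1 = a1, results_analysis2 = a2,
       peptide_matrix = balanced, proteins = mp$proteins, manifest = manifest)
}

#' Orchestrated end-to-end run
#'
#' Single entry point over the whole package, driven by a YAML/JSON
#' configuration (or an equivalent list). Subcommands: `"simulate"`
#' (materialize a synthetic dataset), `"lfq"` and `"itraq"` (run one
#' quantification branch from files), `"compare"` (method-comparison
#' report from two result tables). Outputs are written under `out_dir`
#' together with a JSON run manifest; reruns with the same config and
#' inputs are byte-identical.
#'
#' Config keys -- `inputs`: `psm_table`, `fasta`, `design`, `impurity`
#' (itraq), `results_a`/`results_b` (compare); `params`: overrides of
#' [default_params()]; `simulate`: arguments of [generate_truth()] plus
#' `mode` (`"lfq"`, `"itraq"` or `"both"`) and the simulator's noise and
#' missingness settings.
#'
#' @param config Path to a YAML/JSON config file, or a list.
#' @param subcommand One of `"simulate"`, `"lfq"`, `"itraq"`, `"compare"`.
#' @param out_dir Output directory.
#' @param seed Integer seed overriding the config's.
#' @return Invisible list of result objects; side effect: files and
#'   `manifest.json` under `out_dir`.
#' @export
run_pipeline <- function(config, subcommand = c("lfq", "itraq", "simulate", "compare"),
                         out_dir = ".", seed = NULL) {
  subcommand <- match.arg(subcommand)
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  if (!is.list(cfg)) stop("invalid configuration", call. = FALSE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (is.null(seed)) seed <- if (!is.null(cfg$seed)) cfg$seed else 1L
  params <- if (is.null(cfg$params)) list() else cfg$params
  outputs <- list()
  manifest <- list(subcommand = subcommand, seed = seed, config = cfg)

  if (subcommand == "simulate") {
    sc <- if (is.null(cfg$simulate)) list() else cfg$simulate
    truth_args <- sc[intersect(names(sc), names(formals(generate_truth)))]
    truth_args$seed <- seed
    truth <- do.call(generate_truth, truth_args)
    mode <- if (is.null(sc$mode)) "both" else sc$mode
    if (mode %in% c("lfq", "both")) {
      lfq_args <- sc[intersect(names(sc), names(formals(simulate_lfq)))]
      sim <- do.call(simulate_lfq, c(list(truth = truth, seed = seed + 1L), lfq_args))
      outputs$lfq <- write_simulation(sim, truth, file.path(out_dir, "lfq"))
    }
    if (mode %in% c("itraq", "both")) {
      it_args <- sc[intersect(names(sc), names(formals(simulate_itraq)))]
      it_args$impurity <- default_impurity_matrix()
      sim <- do.call(simulate_itraq, c(list(truth = truth, seed = seed + 2L), it_args))
      outputs$itraq <- write_simulation(sim, truth, file.path(out_dir, "itraq"))
    }
    truth_path <- file.path(out_dir, "truth.tsv")
    utils::write.table(truth$proteins[c("accession", "true_log2_fc", "is_keratin",
                                        "n_peptides")],
                       truth_path, sep = "\t", quote = FALSE, row.names = FALSE)
    outputs$truth <- truth_path
    result <- list(truth = truth)
  } else if (subcommand %in% c("lfq", "itraq")) {
    inp <- cfg$inputs
    if (is.null(inp$psm_table) || !file.exists(inp$psm_table)) {
      stop("missing input PSM table", call. = FALSE)
    }
    psms <- read_psm_table(inp$psm_table, mode = subcommand)
    db <- read_fasta(inp$fasta)
    design <- read_study_design(inp$design)
    if (subcommand == "lfq") {
      result <- run_lfq_pipeline(psms, db, design, params)
      outputs$results <- file.path(out_dir, "lfq_results.tsv")
      write_results(result$results[c("accession", "n_peptides", "log2_ratio",
                                     "p_value", "direction", "method")],
                    outputs$results)
      outputs$protein_table <- file.path(out_dir, "lfq_protein_table.tsv")
      utils::write.table(result$protein_table, outputs$protein_table,
                         sep = "\t", quote = FALSE, col.names = NA)
    } else {
      impurity <- if (!is.null(inp$impurity)) read_impurity_matrix(inp$impurity)
      result <- run_itraq_pipeline(psms, db, design, impurity, params)
      for (nm in c("results_analysis1", "results_analysis2")) {
        outputs[[nm]] <- file.path(out_dir, paste0("itraq_", nm, ".tsv"))
        write_results(result[[nm]][c("accession", "n_peptides", "log2_ratio",
                                     "p_value", "direction", "method")],
                      outputs[[nm]])
      }
      outputs$peptide_matrix <- file.path(out_dir, "itraq_peptide_matrix.tsv")
      utils::write.table(result$peptide_matrix, outputs$peptide_matrix,
                         sep = "\t", quote = FALSE, col.names = NA)
    }
    manifest <- c(manifest, result$manifest)
  } else {  # compare
    inp <- cfg$inputs
    res_a <- read_results(inp$results_a)
    res_b <- read_results(inp$results_b)
    ov <- overlap_counts(list(a = res_a$accession, b = res_b$accession))
    conc <- trend_concordance(res_a, res_b,
                              alpha = merge_params(params)$alpha)
    corr <- tryCatch({
      m <- merge(res_a, res_b, by = "accession", suffixes = c("_a", "_b"))
      correlate_ratios(m$log2_ratio_a, m$log2_ratio_b)
    }, error = function(e) NULL)
    result <- list(overlap = ov, concordance = conc, correlation = corr)
    outputs$report <- file.path(out_dir, "comparison.json")
    jsonlite::write_json(
      list(overlap = ov,
           correlation = corr,
           concordance = list(n_consistent = conc$n_consistent,
                              n_conflicting = conc$n_conflicting,
                              exclusive_a = conc$exclusive_a,
                              exclusive_b = conc$exclusive_b)),
      outputs$report, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    outputs$concordance_table <- file.path(out_dir, "concordance.tsv")
    utils::write.table(conc$table, outputs$concordance_table, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  manifest$outputs <- outputs
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  invisible(result)
}
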