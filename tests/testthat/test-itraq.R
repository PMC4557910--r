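test_that("impurity correction inverts forward mixing exactly", {
  m <- default_impurity_matrix()
  v <- c(120, 4000, 35, 800, 1500, 60, 950, 220)
  observed <- as.numeric(m %*% v)
  expect_lt(max(abs(correct_impurities(observed, m) - v)), 1e-9)
  # identity matrix leaves intensities untouched
  expect_equal(unname(correct_impurities(v, diag(8))), v, ignore_attr = TRUE)
  # random diagonally-dominant mixes round-trip too
  set.seed(5)
  for (i in 1:10) {
    mm <- matrix(runif(64, 0, 0.01), 8, 8)
    diag(mm) <- runif(8, 0.9, 0.95)
    mm <- sweep(mm, 2, pmax(colSums(mm), 1), "/")
    w <- runif(8, 10, 1e4)
    expect_lt(max(abs(correct_impurities(as.numeric(mm %*% w), mm) - w)), 1e-9)
  }
})

test_that("negative correction solutions are re-solved non-negatively", {
  m <- default_impurity_matrix()
  # an observed vector inconsistent with any non-negative truth
  observed <- c(1000, 0, 0, 0, 0, 0, 0, 0)
  plain <- as.numeric(solve(m, observed))
  expect_true(any(plain < 0))
  fixed <- correct_impurities(observed, m, clamp = "nnls")
  expect_true(all(fixed >= 0))
  expect_equal(attr(fixed, "n_clamped"), 1L)
  # the constrained re-solve matches the non-negative least-squares oracle
  oracle <- pracma::lsqnonneg(m, observed)$x
  expect_equal(unname(fixed), oracle, tolerance = 1e-9, ignore_attr = TRUE)
  # and fits at least as well as naive truncation
  trunc <- correct_impurities(observed, m, clamp = "truncate")
  expect_lte(sum((m %*% fixed - observed)^2), sum((m %*% trunc - observed)^2))
})

test_that("zero reporters take the minimal reported intensity", {
  ints <- rbind(c(0, 50, 60, 70, 80, 90, 100, 110),
                c(12, 40, 55, 65, 75, 85, 95, 105))
  sp <- make_spectra(ints)
  out <- substitute_zero_reporters(sp)
  expect_equal(out$reporter_113[1], 12)   # run-wide minimum nonzero
  # per-spectrum scope uses the spectrum's own minimum
  out2 <- substitute_zero_reporters(sp, scope = "spectrum")
  expect_equal(out2$reporter_113[1], 50)
  # no zeros: identity
  expect_identical(substitute_zero_reporters(sp[2, ]), sp[2, ])
  # all-zero spectra are dropped with a warning; an all-zero run is an error
  sp3 <- make_spectra(rbind(rep(0, 8), c(5, rep(1, 7))))
  expect_warning(out3 <- substitute_zero_reporters(sp3), "dropped")
  expect_equal(nrow(out3), 1L)
  expect_error(suppressWarnings(
    substitute_zero_reporters(make_spectra(matrix(0, 2, 8)))), "zero")
})

test_that("co-isolation filtering is strict at the 30% boundary", {
  sp <- make_spectra(matrix(1, 4, 8), coisolation_pct = c(35, 29.9, 30, NA))
  out <- coisolation_filter(sp)
  expect_equal(out$coisolation_pct, 29.9)
  expect_equal(attr(out, "n_missing_coisolation"), 1L)
})

test_that("peptide abundance is the per-channel median over matching spectra", {
  ints <- rbind(c(1, rep(5, 7)), c(2, rep(5, 7)), c(9, rep(5, 7)))
  sp <- make_spectra(ints, sequence = rep("AAAAK", 3))
  tab <- peptide_abundance_itraq(sp)
  expect_equal(nrow(tab), 1L)
  expect_equal(tab[1, "113"], 2)
  # single spectrum: its own values
  one <- peptide_abundance_itraq(make_spectra(matrix(1:8, 1), sequence = "CCCCK"))
  expect_equal(unname(one[1, ]), as.numeric(1:8))
  # oxidized and unmodified forms stay distinct; charge never enters the key
  sp2 <- make_spectra(matrix(1, 2, 8), sequence = rep("MAAAK", 2))
  sp2$modifications <- c("", "1:Oxidation")
  sp2$peptide_key <- peptide_key(sp2$sequence, sp2$modifications)
  expect_equal(nrow(peptide_abundance_itraq(sp2)), 2L)
})

test_that("median peptide abundance is monotone in spectrum intensities", {
  set.seed(9)
  ints <- matrix(runif(5 * 8, 10, 100), 5, 8)
  sp <- make_spectra(ints, sequence = rep("DDDDK", 5))
  base <- peptide_abundance_itraq(sp)
  for (i in 1:5) {
    sp2 <- sp
    sp2$reporter_113[i] <- sp2$reporter_113[i] + 50
    expect_gte(peptide_abundance_itraq(sp2)[1, "113"], base[1, "113"])
  }
})

test_that("reporter fractions and channel balancing satisfy their identities", {
  tab <- matrix(c(rep(3, 8), 1:8), 2, 8, byrow = TRUE,
                dimnames = list(c("p1", "p2"), itraq_channels()))
  fr <- reporter_fractions(tab)
  expect_equal(unname(fr["p1", ]), rep(0.125, 8))
  expect_equal(unname(fr["p2", ]), (1:8) / 36)
  expect_equal(unname(rowSums(fr)), c(1, 1))
  bal <- balance_channels(fr)
  totals <- colSums(bal)
  expect_lt(diff(range(totals)) / mean(totals), 1e-9)
  # balancing an already-balanced table is the identity
  expect_equal(balance_channels(bal), bal)
  # uniformly doubling one channel pre-balance is undone by balancing
  fr2 <- fr; fr2[, 3] <- fr2[, 3] * 2
  expect_equal(balance_channels(fr2), bal)
  # dead channel is an error
  fr3 <- fr; fr3[, 5] <- 0
  expect_error(balance_channels(fr3), "117")
})

test_that("analysis 1 uses unique peptides and flags unquantifiable proteins", {
  design <- default_design("itraq")
  mat <- matrix(c(rep(1, 4), rep(2, 4),
                  rep(1, 4), rep(2, 4),
                  rep(3, 8)), 3, 8, byrow = TRUE,
                dimnames = list(c("u1|", "u2|", "sh|"), itraq_channels()))
  proteins <- data.frame(accession = c("P1", "P2"), n_peptides = c(3L, 1L))
  proteins$peptides <- list(c("u1|", "u2|", "sh|"), "sh|")
  proteins$unique_peptides <- list(c("u1|", "u2|"), character(0))
  a1 <- protein_quant_analysis1(mat, proteins, design)
  expect_equal(a1$accession, "P1")
  expect_equal(a1$log2_ratio, 1)
  expect_equal(attr(a1, "unquantified"), "P2")
  # all channels identical: flat ratio, p = 1
  flat <- matrix(5, 2, 8, dimnames = list(c("u1|", "u2|"), itraq_channels()))
  pf <- proteins[1, ]
  af <- protein_quant_analysis1(flat, pf, design)
  expect_equal(af$log2_ratio, 0)
  expect_equal(af$p_value, 1)
  expect_equal(af$direction, "flat")
})

test_that("analysis 2 averages peptide ratios before the log transform", {
  design <- default_design("itraq")
  # peptide ratios 2 and 4 -> protein ratio 3 -> log2(3)
  mat <- rbind(`a|` = c(rep(1, 4), rep(2, 4)),
               `b|` = c(rep(1, 4), rep(4, 4)))
  colnames(mat) <- itraq_channels()
  proteins <- data.frame(accession = "P1", n_peptides = 2L)
  proteins$peptides <- list(c("a|", "b|"))
  proteins$unique_peptides <- proteins$peptides
  a2 <- protein_quant_analysis2(mat, proteins, design)
  expect_equal(a2$log2_ratio, log2(3), tolerance = 1e-12)
  expect_equal(round(a2$log2_ratio, 5), 1.58496)
})

test_that("both strategies collapse to the truth without noise", {
  truth <- generate_truth(n_proteins = 25, peptides_per_protein = c(2, 5),
                          frac_differential = 0.4, seed = 41)
  sim <- simulate_itraq(truth, impurity = default_impurity_matrix(),
                        noise_sd_log2 = 0, p_zero_reporter = 0,
                        coisolation_beta = c(1, 60),
                        spectra_per_peptide = c(2, 2), seed = 42)
  out <- run_itraq_pipeline(sim$psms, truth_db(truth), sim$design,
                            impurity = sim$impurity)
  fc <- setNames(truth$proteins$true_log2_fc, truth$proteins$accession)
  a1 <- setNames(out$results_analysis1$log2_ratio, out$results_analysis1$accession)
  a2 <- setNames(out$results_analysis2$log2_ratio, out$results_analysis2$accession)
  expect_gt(length(a1), 15)
  expect_lt(max(abs(a1 - fc[names(a1)])), 1e-9)
  expect_lt(max(abs(a2 - fc[names(a2)])), 1e-9)
  expect_lt(max(abs(a1 - a2[names(a1)])), 1e-9)
})

test_that("ratio accuracy improves with more peptides per protein", {
  mae <- sapply(c(2, 8), function(k) {
    truth <- generate_truth(n_proteins = 60, peptides_per_protein = c(k, k),
                            frac_differential = 1, seed = 51)
    sim <- simulate_itraq(truth, noise_sd_log2 = 0.1, p_zero_reporter = 0,
                          coisolation_beta = c(1, 60),
                          spectra_per_peptide = c(1, 1), seed = 52)
    out <- run_itraq_pipeline(sim$psms, truth_db(truth), sim$design)
    fc <- setNames(truth$proteins$true_log2_fc, truth$proteins$accession)
    est <- setNames(out$results_analysis1$log2_ratio,
                    out$results_analysis1$accession)
    mean(abs(est - fc[names(est)]))
  })
  expect_lt(mae[2], mae[1])
})

test_that("labeling efficiency counts termini and lysines correctly", {
  full <- make_psms(3, mode = "itraq", sequence = c("AAAK", "CCCR", "DKDK"),
                    modifications = c("0:iTRAQ8plex;4:iTRAQ8plex",
                                      "0:iTRAQ8plex",
                                      "0:iTRAQ8plex;2:iTRAQ8plex;4:iTRAQ8plex"))
  eff <- labeling_efficiency(full)
  expect_equal(eff$pct_nterm_labeled, 100)
  expect_equal(eff$pct_k_labeled, 100)
  # 3 of 4 K-containing peptides labeled on K, 5 of 6 peptides N-term labeled
  mixed <- make_psms(6, mode = "itraq",
                     sequence = c("AAAK", "CCCK", "DDDK", "EEEK", "FFFR", "GGGR"),
                     modifications = c("0:iTRAQ8plex;4:iTRAQ8plex",
                                       "0:iTRAQ8plex;4:iTRAQ8plex",
                                       "0:iTRAQ8plex;4:iTRAQ8plex",
                                       "0:iTRAQ8plex",
                                       "0:iTRAQ8plex",
                                       ""))
  eff2 <- labeling_efficiency(mixed)
  expect_equal(eff2$pct_k_labeled, 75)
  expect_equal(eff2$pct_nterm_labeled, 100 * 5 / 6)
  # empty input is undefined
  expect_true(is.na(labeling_efficiency(full[0, ])$pct_nterm_labeled))
})
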