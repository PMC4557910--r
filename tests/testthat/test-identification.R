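test_that("PSM filters enforce each identification criterion exactly once", {
  ok <- make_psms(1)
  violators <- rbind(
    transform(make_psms(1), delta_mass_ppm = 6),      # mass deviation
    transform(make_psms(1), q_value = 0.02),          # FDR
    transform(make_psms(1), rank = 6L),               # rank
    transform(make_psms(1), sequence = "ELVXSK"),     # unknown amino acid
    transform(make_psms(1), candidate_accessions = "")) # unmappable
  out <- filter_psms(rbind(violators, ok))
  expect_equal(nrow(out), 1L)
  expect_equal(out$delta_mass_ppm, ok$delta_mass_ppm)
  # boundary: deviation exactly at the cutoff is removed (strict <)
  expect_equal(nrow(filter_psms(transform(make_psms(1), delta_mass_ppm = 5))), 0L)
  expect_equal(nrow(filter_psms(make_psms(1)[0, ])), 0L)
})

test_that("tightening any filter threshold never enlarges the surviving set", {
  set.seed(42)
  n <- 200
  psms <- make_psms(n,
                    delta_mass_ppm = runif(n, -10, 10),
                    q_value = runif(n, 0, 0.05),
                    rank = sample(1:8, n, replace = TRUE))
  base <- filter_psms(psms, max_ppm = 5, max_q = 0.01, max_rank = 5)
  for (args in list(list(max_ppm = 3), list(max_q = 0.005), list(max_rank = 2))) {
    tighter <- do.call(filter_psms, c(list(psms = psms), args))
    expect_true(all(tighter$spectrum_id %in% base$spectrum_id) ||
                  nrow(tighter) <= nrow(base))
    expect_lte(nrow(tighter), nrow(base))
  }
})

test_that("spectrum candidate resolution picks the majority sequence", {
  # same precursor, two interpretations: A seen in 5 samples, B in 2
  a <- make_psms(5, run_id = paste0("s", 1:5), sequence = "AAAAK",
                 precursor_mz = 500.000, retention_time = 50)
  b <- make_psms(2, run_id = paste0("s", 6:7), sequence = "CCCCK",
                 precursor_mz = 500.001, retention_time = 50.1)
  out <- resolve_spectrum_candidates(rbind(a, b))
  expect_setequal(unique(out$sequence), "AAAAK")
  expect_equal(nrow(out), 5L)

  # 3 vs 3 tie broken by XCorr
  a <- make_psms(3, run_id = paste0("s", 1:3), sequence = "AAAAK", xcorr = 2.5,
                 precursor_mz = 600, retention_time = 80)
  b <- make_psms(3, run_id = paste0("s", 4:6), sequence = "CCCCK", xcorr = 1.9,
                 precursor_mz = 600.002, retention_time = 80.2)
  out <- resolve_spectrum_candidates(rbind(a, b))
  expect_setequal(unique(out$sequence), "AAAAK")

  # a single interpretation passes through unchanged
  single <- make_psms(2, run_id = c("s1", "s2"))
  expect_identical(resolve_spectrum_candidates(single), single)

  # distinct spectra (far apart) are never merged
  far <- rbind(make_psms(1, sequence = "AAAAK", precursor_mz = 500),
               make_psms(1, sequence = "CCCCK", precursor_mz = 900))
  expect_equal(nrow(resolve_spectrum_candidates(far)), 2L)
})

test_that("peptide grouping collapses identical modification multisets", {
  psms <- rbind(
    make_psms(1, run_id = "s1", sequence = "MPEPTIDEK",
              modifications = "1:Oxidation"),
    make_psms(1, run_id = "s2", sequence = "MPEPTIDEK",
              modifications = "4:Oxidation"),   # same multiset, other position
    make_psms(1, run_id = "s1", sequence = "MPEPTIDEK",
              modifications = "1:Oxidation;4:Oxidation"))  # different multiset
  pg <- build_peptide_groups(psms)
  expect_equal(nrow(pg$peptides), 2L)
  expect_true(pg$observed[peptide_key("MPEPTIDEK", "1:Oxidation"), "s2"])
})

test_that("identified-without-area is preserved as NA, distinct from absent", {
  psms <- rbind(make_psms(1, run_id = "s1", precursor_area = 100),
                transform(make_psms(1, run_id = "s2"), precursor_area = NA_real_))
  pg <- build_peptide_groups(psms)
  expect_equal(unname(pg$area[1, c("s1", "s2")]), c(100, NA))
  expect_true(all(pg$observed[1, c("s1", "s2")]))
})

test_that("keratin-derived peptides are removed entirely", {
  db <- make_db(K1 = list(seq = "AAAKCCCK", desc = "Keratin, type II cytoskeletal 1"),
                P1 = list(seq = "AAAKDDDK", desc = "ordinary protein"))
  pg <- make_peptide_groups(list(
    list(sequence = "AAAK", acc = "K1;P1", observed = TRUE, area = 1),  # shared
    list(sequence = "CCCK", acc = "K1", observed = TRUE, area = 1),     # keratin only
    list(sequence = "DDDK", acc = "P1", observed = TRUE, area = 1)),
    samples = "s1")
  out <- exclude_keratins(pg, db)
  expect_equal(out$peptides$sequence, "DDDK")
  # no keratins in the database: identity
  db2 <- make_db(P1 = list(seq = "AAAKDDDK", desc = "ordinary"))
  expect_identical(exclude_keratins(pg, db2), pg)
})

test_that("group-consistency filter applies the 75% rule per group", {
  design <- lfq_design_4v4()
  samples <- names(design$group_of)
  obs <- function(pTa, pT2) c(pTa, pT2)
  pg <- make_peptide_groups(list(
    list(sequence = "AAAK", acc = "P1",
         observed = obs(c(TRUE, TRUE, TRUE, FALSE), rep(FALSE, 4)), area = 1),  # 3/4 one group
    list(sequence = "CCCK", acc = "P1",
         observed = obs(c(TRUE, TRUE, FALSE, FALSE), c(TRUE, TRUE, FALSE, FALSE)), area = 1), # 2/4 both
    list(sequence = "DDDK", acc = "P1",
         observed = obs(rep(TRUE, 4), rep(FALSE, 4)), area = 1)),  # 4/4
    samples = samples)
  out <- consistency_filter(pg, design)
  expect_setequal(out$peptides$sequence, c("AAAK", "DDDK"))
  # strict mode demands strictly more than 75%: 3/4 now fails
  strict <- consistency_filter(pg, design, strict = TRUE)
  expect_setequal(strict$peptides$sequence, "DDDK")
})

test_that("parsimony inference selects a minimal explaining protein set", {
  db <- make_db(A = list(seq = paste0("AAAK", "CCCK")),
                B = list(seq = paste0("CCCK", "DDDK")))
  pg <- make_peptide_groups(list(
    list(sequence = "AAAK", acc = "A", observed = TRUE),
    list(sequence = "CCCK", acc = "A;B", observed = TRUE)),
    samples = "s1")
  out <- infer_proteins_occam(pg, db)
  expect_equal(out$accession, "A")
  expect_equal(out$n_peptides, 2L)
  # B never appears: the shared peptide is assigned to A
  expect_setequal(unlist(out$peptides), pg$peptides$key)

  # proteins explaining identical peptide sets: lexicographically first wins
  pg2 <- make_peptide_groups(list(
    list(sequence = "AAAK", acc = "A;B", observed = TRUE),
    list(sequence = "CCCK", acc = "A;B", observed = TRUE)),
    samples = "s1")
  out2 <- infer_proteins_occam(pg2, db)
  expect_equal(out2$accession, "A")

  # unresolvable accession is an error
  pg3 <- make_peptide_groups(list(
    list(sequence = "AAAK", acc = "ZZZ", observed = TRUE)), samples = "s1")
  expect_error(infer_proteins_occam(pg3, db), "ZZZ")
})

test_that("assignments after parsimony partition the peptide set", {
  set.seed(7)
  for (rep in 1:5) {
    n_prot <- sample(4:8, 1)
    prots <- LETTERS[seq_len(n_prot)]
    peps <- lapply(1:15, function(i) {
      list(sequence = paste0(paste(sample(c("A", "C", "D", "E"), 6, TRUE),
                                   collapse = ""), i, "K"),
           acc = paste(sample(prots, sample(1:3, 1)), collapse = ";"),
           observed = TRUE)
    })
    pg <- make_peptide_groups(peps, samples = "s1")
    db <- do.call(make_db, setNames(lapply(prots, function(p) list(seq = "MK")), prots))
    out <- infer_proteins_occam(pg, db)
    assigned <- unlist(out$peptides)
    expect_setequal(assigned, pg$peptides$key)
    expect_equal(anyDuplicated(assigned), 0L)
    expect_true(all(out$n_peptides >= 1L))
  }
})

test_that("greedy cover size matches the exhaustive minimum on small instances", {
  set.seed(11)
  for (rep in 1:10) {
    n_prot <- sample(3:10, 1)
    prots <- LETTERS[seq_len(n_prot)]
    cand <- lapply(1:12, function(i) sample(prots, sample(1:3, 1)))
    peps <- lapply(seq_along(cand), function(i) {
      list(sequence = paste0("PEP", i, "K"),
           acc = paste(cand[[i]], collapse = ";"), observed = TRUE)
    })
    pg <- make_peptide_groups(peps, samples = "s1")
    db <- do.call(make_db, setNames(lapply(prots, function(p) list(seq = "MK")), prots))
    out <- infer_proteins_occam(pg, db)
    expect_equal(nrow(out), brute_force_min_cover(cand))
  }
})

test_that("the multiple-peptide rule retains >=2-peptide groups and counts singles", {
  proteins <- data.frame(accession = c("A", "B", "C", "D"),
                         n_peptides = c(1L, 2L, 3L, 4L))
  proteins$peptides <- list("p1", c("p2", "p3"), c("p4", "p5", "p6"),
                            c("p7", "p8", "p9", "p10"))
  proteins$unique_peptides <- proteins$peptides
  out <- require_min_peptides(proteins)
  expect_setequal(out$proteins$accession, c("B", "C", "D"))
  expect_equal(out$n_single, 1L)
  expect_equal(out$histogram, c(`1` = 1L, `2` = 1L, `3` = 1L, `>=4` = 1L))
  empty <- require_min_peptides(proteins[0, ])
  expect_equal(nrow(empty$proteins), 0L)
})
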