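# quantproteo

Two complete quantitative shotgun-proteomics workflows, from PSM-level
search-engine exports to differential-expression calls, built to be compared
against each other on the same samples:

* **Label-free quantification (LFQ)** — MS1 precursor peak areas per run,
  two-mechanism missing-value handling, parts-per-million normalization,
  protein rollup by summation, and an independent-samples t-test on log2
  abundances.
* **8-plex isobaric reporter-ion quantification (iTRAQ)** — isotope-impurity
  correction, zero-reporter substitution, a co-isolation interference
  filter, median peptide abundances over spectra, reporter-fraction
  normalization, channel balancing to 12.5%, and two protein-rollup
  strategies (averaged abundances vs averaged peptide ratios).

Both branches share one identification layer: PSM filters (mass deviation
< 5 ppm, FDR < 1%, rank ≤ 5, no unknown residues), cross-run spectrum
resolution, keratin-contaminant exclusion, a 75% group-consistency rule,
parsimonious (Occam-razor) protein inference, and the ≥ 2-peptide rule.
A ground-truthed synthetic-data generator and method-comparison metrics
(identification overlaps, sequence coverage, ratio correlation/regression,
regulation-trend concordance, modification prevalence) make every stage
testable without any external download. The motivating use case is tumor
tissue profiling — e.g. non-muscle-invasive (pTa) vs muscle-invasive (pT2+)
bladder cancer, 4 samples per group.

## The statistics in brief

For LFQ, each peptide's normalized area is
`norm = area / total_area_in_sample × 10^6`, protein abundance is the sum of
its assigned peptides' normalized areas, and the reported effect is
`log2(case/control) = log2(mean case) − log2(mean control)` with a two-sided
Student t-test on per-sample log2 abundances.

For iTRAQ, observed reporter intensities are unmixed by solving
`M · x = observed` (with a non-negative least-squares re-solve when the
plain solution goes negative), each peptide's channel profile is the median
over its spectra expressed as reporter fractions `f_c = I_c / Σ I`, and
channels are rescaled so each contributes 12.5% of total share. Analysis 1
averages the balanced values of a protein's unique peptides per channel and
tests channel-level log2 abundances; analysis 2 averages the per-peptide
case/control ratios and takes the log afterwards, with a z-test of each
protein's log2 ratio against the empirical ratio population.

## Worked example

Simulate an 8-plex experiment with known fold changes, run the full
labelled pipeline (including impurity correction), and inspect the calls:

```r
library(quantproteo)

truth <- generate_truth(n_proteins = 60, peptides_per_protein = c(2, 6),
                        frac_differential = 0.4, frac_keratin = 0.05, seed = 42)
sim <- simulate_itraq(truth, impurity = default_impurity_matrix(),
                      noise_sd_log2 = 0.3, p_zero_reporter = 0.01, seed = 43)
out <- run_itraq_pipeline(sim$psms, truth_db(truth), sim$design,
                          impurity = default_impurity_matrix())
res <- out$results_analysis1
head(res[order(res$p_value), c("accession", "n_peptides", "log2_ratio",
                               "p_value", "direction")], 5)
#>    accession n_peptides log2_ratio  p_value direction
#> 13  SYNP0013          6       1.51 3.56e-09        up
#> 14  SYNP0014          6      -1.36 5.64e-08      down
#> 2   SYNP0002          5      -1.72 2.90e-07      down
#> 4   SYNP0004          6      -1.89 3.40e-07      down
#> 1   SYNP0001          4       1.88 5.48e-07        up
```

57 of the 60 proteins are reported (keratin contaminants are excluded and
proteins left with fewer than two peptides are dropped); 23 reach p < 0.05,
and the mean absolute error of the estimated log2 ratios against the
simulated truth is 0.086 at this noise level. `log2_ratio` is the
case-over-control fold change on the log2 scale — `1.51` means the protein
is about 2.8-fold higher in the case group — and `direction` summarizes its
sign.

File-based runs use the same machinery through a single config
(`run_pipeline(config, "lfq" | "itraq" | "simulate" | "compare", out_dir)`),
or the shell wrapper in `inst/scripts/quantproteo.R`. Each run writes its
result tables plus a JSON manifest with per-stage counts.

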