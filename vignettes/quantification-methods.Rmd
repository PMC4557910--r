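---
title: "Methods: label-free and reporter-ion quantification in quantproteo"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: label-free and reporter-ion quantification in quantproteo}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(quantproteo)
```

## Scope and model

quantproteo implements two relative-quantification workflows that start
from the same kind of evidence — peptide-spectrum matches (PSMs) exported
by a database-search post-processor — and end in per-protein log2 fold
changes with p-values, for a two-group design (default 4 vs 4, modelled on
a non-muscle-invasive vs muscle-invasive bladder-tumor comparison):

* **Label-free (LFQ)**: each sample is a separate LC-MS/MS run; the
  quantitative signal is the MS1 precursor peak area of each peptide.
* **8-plex reporter-ion (iTRAQ)**: all eight samples are labelled,
  multiplexed and measured in one run; the signal is the set of eight
  low-mass reporter-ion intensities released on fragmentation.

Both share one identification layer. The package assumes identification
scoring has already happened: q-values, mass errors, ranks and XCorr come
in with the PSMs and are filtered, never re-estimated.

## Identification layer

PSMs are retained when |Δm| < 5 ppm, q < 0.01, rank ≤ 5, the sequence has
no unknown residue (X) and at least one candidate accession resolves.
These are the field's conventional high-confidence thresholds and are all
configurable (`default_params()`). FDR is filtered per run and by design
not re-assessed after merging runs.

In the multi-run label-free case the same spectrum — keyed by precursor
m/z and retention time within tolerance — can receive different sequence
interpretations in different runs. `resolve_spectrum_candidates()` keeps
the interpretation seen in the most samples, breaking ties by best XCorr
and then lexicographically. The matching tolerances (10 ppm, 0.5 min) are
our own defaults chosen to be wide enough for inter-run drift on a modern
Orbitrap and narrow enough that distinct tryptic peptides essentially
never collide; both are configurable.

Peptides are grouped by sequence plus modification *multiset*: the same
modifications at different positions collapse to one group, and charge
never enters the key. Any peptide mapping to a protein whose description
matches the contaminant pattern (default `"keratin"`) is removed entirely,
even if it also maps to non-contaminant proteins — contaminant signal must
not leak into quantification through shared peptides.

The **consistency rule** keeps a peptide only if observed in at least 75%
of the samples of at least one group. With 4 samples per group, "at least
75%" admits 3/4 while "more than 75%" demands 4/4; we adopt ≥ (3/4 passes)
as the default because it describes what a consistency filter is for —
tolerating one dropout — and expose `strict_consistency` for the other
reading.

**Protein inference** follows the parsimony (Occam-razor) principle. The
principle names an objective, not an algorithm, so we use greedy set
cover — iteratively select the accession explaining the most unexplained
peptides — which is the standard choice and provably near-optimal; on
every instance small enough to check exhaustively (≤ 12 candidate
proteins) the test suite verifies the greedy cover size equals the true
minimum. Each shared peptide is then assigned to exactly one selected
protein (most total peptide evidence, ties by accession order), making
assignments a partition — a property the rollups rely on. Proteins with
fewer than 2 peptides are excluded from reporting but counted, since
single-peptide identifications carry both identification and
quantification risk.

## Label-free branch

Two missingness mechanisms are distinguished and treated differently,
which is why the readers never coerce empty cells to zero:

* *identified but not integrated* (a known failure mode of peak
  integration software): imputed with the mean of the peptide's available
  areas in the same group; if the whole group lacks values the cell falls
  back to 0 with a logged warning;
* *not identified in that run*: set to 0 — absence of evidence is treated
  as absence of signal at this stage.

Each sample column is then ppm-normalized (`area / column total × 10^6`),
protein abundance is the sum of assigned peptide areas, and the effect is
`log2(mean case) − log2(mean control)` with a two-sided independent-samples
t-test on per-sample log2 abundances. The t-test flavour is pooled-variance
Student by default (Welch via `ttest_var_equal = FALSE`); the per-sample
reading is the only one consistent with an independent-samples test on a
4 vs 4 design. Zeros are replaced by half the protein's smallest nonzero
abundance before the log transform (a standard pseudo-floor that keeps the
test defined without inventing signal); a protein with a zero group mean
gets an undefined ratio rather than ±∞ and is excluded from significance
calls. Raw p < 0.05 is the default significance criterion, with
Benjamini-Hochberg reporting available through `adjust = "BH"` — advisable
whenever the protein list is long.

## Reporter-ion branch

Spectrum-level processing happens in this order:

1. **Isotope-impurity correction.** Each label leaks a known fraction of
   its signal into neighbouring reporters; with column-stochastic impurity
   matrix M, the observed vector is M·x and we solve for x. When the
   plain solve returns negative components (possible whenever the observed
   vector is inconsistent with any non-negative truth), we re-solve under
   a non-negativity constraint (non-negative least squares) instead of
   naively truncating: truncation biases the remaining channels, whereas
   the constrained solution is the closest physically admissible one.
   Naive truncation remains available for comparison
   (`clamp_policy = "truncate"`), and clamp events are counted in the run
   manifest. The matrix is validated at load (column sums in (0, 1],
   diagonal dominance per column, invertibility). The bundled default
   matrix is **synthetic** — vendor-style satellite structure including the
   mass-120 gap of the 113–121 series — because real per-batch certificate
   values ship with each reagent kit.
2. **Zero-reporter substitution.** A zero reporter means the tag was not
   observed; it is replaced by the minimal reported intensity. "Minimal"
   is ambiguous in scope, so the default is the global minimum nonzero
   intensity of the run (stable, and what a run-level floor means); a
   per-spectrum alternative is available (`zero_scope = "spectrum"`).
   All-zero spectra are dropped with a warning.
3. **Co-isolation filter.** Spectra with co-isolation interference ≥ 30%
   are excluded (strict `<` at the boundary, reading "below 30%"
   literally); spectra with no co-isolation value are conservatively
   excluded and counted separately.

Peptide abundance per channel is the **median** over the peptide's spectra
(outlier resistance), each row is expressed as reporter fractions, and
channels are balanced so each contributes 12.5% of total share. Because a
proper fraction table carries one unit of share per peptide row, the
balancing target is `n_peptides / 8` per channel; with that target the
operation is idempotent and exactly undoes a uniform per-channel loading
bias, which a target tied to the perturbed grand total would not.

Protein quantification uses **unique peptides only** (unique relative to
the selected protein set). Two strategies are implemented:

* **Analysis 1** (primary): per-channel protein abundance is the mean of
  its unique peptides' balanced values; ratio of log2 group means; t-test
  across channels.
* **Analysis 2**: per-peptide ratio of case-channel mean over
  control-channel mean; protein ratio is the mean of peptide ratios,
  log2-transformed *after* averaging. The accompanying "normal
  distribution of the ratios" p-value is interpreted here as a z-test of
  each protein's log2 ratio against the empirical mean and SD of all
  protein log2 ratios — i.e. an outlier probability within the ratio
  population, not a replicate-based test. This is an interpretation, and
  it is the reason analysis 1 is the primary strategy.

A third rollup, `rollup_peptide_log2_ratios()` (mean of peptide-level log2
ratios), exists because published peptide-level worked examples use it;
for four of the five bundled conflicting-trend proteins it reproduces the
published protein values at two decimals, and for the fifth it gives
−0.05 vs a printed −0.06 — the package reports what it computes.

## Synthetic data: what it emulates and what it does not

`generate_truth()` + `simulate_lfq()` / `simulate_itraq()` produce
desk-scale datasets with known per-protein log2 fold changes,
multiplicative log-normal intensity noise (the standard model for MS
intensities; specified as `2^N(0, sd)` on the log2 scale), both LFQ
missingness mechanisms, zero reporters, Beta-distributed co-isolation,
shared peptides, keratin contaminants and filter-violating junk PSMs.
Proteins are 200–600 residues assembled from their own tryptic-like
peptides plus unobserved filler peptides, so coverage computations behave
realistically.

One generator choice deserves emphasis: compositional normalizations can
only recover fold changes exactly when total signal is balanced between
groups, so differential proteins are created in **+e/−e pairs** with equal
peptide counts and pairwise-matched base areas, and shared peptides are
restricted to non-differential proteins. This makes the noiseless
end-to-end recovery tests exact (≤ 1e-9 for both branches) and mirrors the
approximate global balance real normalization assumes. The marginal effect
distribution is still uniform over the requested range.

What the generator does *not* emulate: intensity-dependent missingness,
retention-time drift, ratio compression from co-isolated background
leaking into reporters (co-isolation here only gates spectra), correlated
peptide noise within a protein, and real sequence homology (shared
peptides are implanted, not homologous). Passing the recovery and
agreement tests therefore demonstrates the pipelines' internal
correctness — not that real tissue data would behave this well.

## Numerical choices and degenerate inputs

* Exactness tolerances in tests are 1e-9 absolute on log2 ratios;
  balancing/normalization identities are checked to 1e-9 relative.
* t-test degeneracies are pinned: all values identical → p = 1 (nothing to
  detect); zero variance in both groups with different means → p
  undefined (`NA`), never 0.
* Ties in parsimony are broken deterministically (evidence count
  descending, then accession ascending), so reruns are byte-identical.
* Readers accept decimal commas in numeric cells (as printed tables often
  carry) and normalize to dot-decimal internally; result tables are
  written at full double precision (`%.17g`) so they round-trip
  losslessly.
* The worked examples, acceptance checks and test suite use deliberately
  small problem sizes — 8–60 proteins for exactness properties, 500
  proteins for the strategy-agreement measurement, 1000 proteins for the
  null calibration of the t-test (empirical type-I error 0.05 ± 0.02) —
  sizes at which every property is checkable in seconds while the
  estimators' asymptotics are already visible.

## Known limitations

* No peak integration, spectral search or FDR estimation — PSM tables are
  the interface, matching how these pipelines sit downstream of search
  engines in practice.
* No match-between-runs or retention-time alignment in the LFQ branch.
* No correction of iTRAQ ratio compression beyond impurity correction.
* The channel layout is the 8-plex series; the operations generalize to
  other plexes but are untested beyond 8.
* The analysis-2 p-value is population-referenced (see above) and should
  not be mixed with the replicate-based analysis-1 p-values in downstream
  multiple-testing corrections.
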