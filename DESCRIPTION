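Package: quantproteo
Title: Label-Free and 8-Plex Isobaric Reporter-Ion Quantitative Proteomics Pipelines
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reusable pipelines for two shotgun-proteomics quantification
    strategies applied to the same peptide-spectrum-match (PSM) evidence:
    intensity-based label-free quantification (MS1 precursor peak areas,
    parts-per-million normalization, sum rollup) and 8-plex isobaric
    reporter-ion (iTRAQ) quantification (isotope-impurity correction,
    co-isolation filtering, reporter-fraction normalization, channel
    balancing, two protein-rollup strategies). Includes peptide-level
    identification filtering, parsimonious (Occam-razor) protein inference,
    keratin-contaminant exclusion, differential-expression testing,
    method-comparison metrics (identification overlaps, sequence coverage,
    ratio correlation, regulation-trend concordance, modification
    prevalence), and a ground-truthed synthetic-data generator for
    benchmarking both branches end to end.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    pracma,
    stats,
    utils,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
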