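Package: panelcnv
Title: Copy-Number Variant Detection for Multiplex Amplicon Sequencing Panels
Version: 0.1.0
Authors@R:
    person("Paco", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Detects copy-number variants (CNVs) from per-amplicon read counts
    produced by multiplex amplicon sequencing panels. Raw counts are normalized
    through a primer-pool share, stable-reference scaling and cross-sample
    median-ratio chain to normalized read counts (NRC) centered on 1, then
    segmented by per-patient z-scores with a one-tailed normal threshold, a
    two-stage ratio that removes first-pass CNV amplicons from the ratio
    denominators, and a single-gap merge heuristic. Includes control-sample
    mode, CUSUM and Loess diagnostic tracks, a tumor-cell-fraction dilution
    simulator, a synthetic run generator for validation, and VCF/TSV export.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
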