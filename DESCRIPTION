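Package: fibrascope
Title: Metagenomic Profiling and Crossover Statistics for Dietary-Fiber
    Intervention Trials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantifies shotgun-metagenomic gene and metagenomic-species (MSP)
    profiles and analyses them in a two-period crossover dietary intervention.
    Implements shared-read attribution to a gene catalog, downsizing to a fixed
    mapped-read depth, FPKM-style gene frequencies, marker-gene MSP abundances
    with a 10 percent detection rule, MSP-restricted KEGG-module/GMM/CAZyme
    carriage, gene and MSP richness, Bray-Curtis dissimilarity, a rank-based
    bread-by-visit interaction screen with Benjamini-Hochberg correction,
    per-bread Wilcoxon signed-rank tests, Cliff's delta effect sizes with
    magnitude grades, delta-delta Spearman correlations, and clinical
    derivations (HOMA-IR, Friedewald LDL, postprandial areas under the curve,
    estimated group differences). A synthetic-data generator emulates the
    crossover study design end-to-end, including planted effects calibrated to
    Cliff's-delta targets and clinical variables coupled to planted features.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr,
    jsonlite
Config/testthat/edition: 3
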