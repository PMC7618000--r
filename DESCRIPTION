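Package: dcmburden
Title: Sex-Stratified Rare-Variant Burden and Penetrance Analysis for
    Dilated Cardiomyopathy
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Gene-based rare-variant analysis of dilated cardiomyopathy (DCM)
    stratified by sex. Variants are qualified by mechanism-aware consequence
    class (loss-of-function, missense, or protein-altering per gene), strict
    population-frequency rarity, variant-level quality control including an
    exact Hardy-Weinberg test, and a constitutive-exon restriction for TTN
    truncating variants. Per-gene carrier counts are compared between female
    and male cases with an exact conditional test (two-sided Fisher p,
    conditional maximum-likelihood odds ratio, exact confidence interval)
    under Benjamini-Hochberg false-discovery-rate control, and sex-stratified
    penetrance is estimated cross-sectionally from case versus population
    carrier frequencies with Monte-Carlo interval propagation. A synthetic
    cohort generator with known carrier frequencies and sex-specific
    penetrance makes every stage testable without access to patient data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    tools,
    vcfR,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
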