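Package: cmspectrum
Title: Rare-Variant Collapsing Tests and Biallelic Case Meta-Analysis for
    Cardiomyopathy Genes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Implements a two-arm analysis of the dominance-recessiveness
    spectrum in cardiomyopathy genes. The association arm runs mask-based
    rare-variant collapsing tests under a dominant model: variant
    classification (LOFTEE-style protein-truncating classes, a
    tool-consensus missense deleteriousness score, gnomAD-style POPMAX
    frequencies), a 22-mask grid crossing two frequency filters with a
    consequence/deleteriousness ladder, score tests with saddlepoint
    approximation for case-control imbalance, Firth bias-reduced logistic
    re-estimation of effect sizes, Cauchy (ACAT) omnibus aggregation across
    masks and Benjamini-Hochberg FDR. The case arm analyses curated
    biallelic patient series: Kaplan-Meier freedom-from-event curves, Cox
    proportional-hazards contrasts between causal genes, onset comparisons
    (two-tailed z and Wilcoxon rank-sum tests), outcome tallies, zygosity
    classification for compound heterozygotes and ClinGen-style estimated
    LOD scores, plus per-population heterozygous-LOF carrier prevalence and
    a biallelic-PTV screen. A synthetic-data module generates every input
    with known ground truth (Hardy-Weinberg rare-variant cohorts with
    planted carrier effects, censored case series, trio pedigrees).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    methods,
    tools,
    survival,
    Matrix,
    data.table,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    optparse
Config/testthat/edition: 3
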