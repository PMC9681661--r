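Package: mficyto
Title: Compartmental Immune Profiling of the Maternal-Fetal Interface by Mass Cytometry
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for single-cell mass cytometry (CyTOF) analysis of the
    mouse maternal-fetal interface across gestation. Provides a synthetic-data
    generator with full ground truth (congenic CD45.1/CD45.2 origin channels, an
    injected-antibody endovascular label, gestational abundance trends with a
    configurable cross-over day, batch distortions with anchor samples, and a
    perturbation arm); preprocessing (arcsinh transform, anchor-based quantile
    normalization, capped subsampling); rule-based gating (viability, maternal/fetal
    origin, endovascular vs. tissue compartment at an arcsinh threshold of 3.5,
    antibody-leakage QC); graph-based clustering with metaclustering, threshold
    splits and canonical Ly-6C monocyte classes; compositional statistics
    (cell-fraction tables, Bray-Curtis dissimilarity, Fisher linear discriminant
    projection, Z-score cross-over detection, condition log-ratios); and gestational
    models (embryonic-day regression with early/late windows,
    heteroskedasticity-robust trend regression with quadratic terms, differential
    marker expression with Bonferroni correction, variance-aware ANOVA dispatch with
    Tukey-HSD or Games-Howell post hocs, and a Taylor-series ratio test).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    igraph,
    mclust,
    car,
    data.table
Suggests:
    testthat (>= 3.0.0),
    vegan,
    MASS,
    sandwich,
    cluster,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
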