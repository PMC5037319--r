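Package: pdxscreen
Title: Ex Vivo Drug-Screen and Genomic Admixture Analysis for Patient-Derived Tumor Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis toolkit for pharmacogenomic screens run on patient-derived
    tumor xenograft (PDTX) explants and their short-term cultures (PDTCs).
    Normalizes plate-based viability readouts against positive/negative controls,
    fits monotone (isotonic) dose-response curves with trapezoid AUC, spline IC50
    and percent-dose IC50 summaries, classifies responses against eight canonical
    response patterns, and scores two-drug combinations against the Bliss
    independence model via exact bivariate isotonic (bimonotone) projection.
    Also provides the supporting genomics utilities for xenograft samples:
    a loess calibration mapping read-level human/mouse admixture to true human
    DNA content, tumor-purity estimation from variant allele fractions in
    copy-loss regions, purity correction and five-state calling of segmented
    copy-number log-ratios, variant QC filters, the MATH intra-tumor
    heterogeneity score, clonality-analysis input preparation, credible-interval
    cluster-shift flagging, and promoter methylation scores from bisulfite CpG
    counts. A synthetic-data module generates every input type with known ground
    truth for end-to-end testing and parameter-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr (>= 1.1.0),
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
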