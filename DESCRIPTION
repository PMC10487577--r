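Package: msfinger
Title: Whole-Cell MALDI-TOF Protein Mass Fingerprint Classification and
    Phylogenetic Concordance
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for whole-cell MALDI-TOF mass-spectrometry
    protein fingerprints of bacterial isolates. Resamples exported peak
    tables onto a fixed 1 Da m/z grid (2-20 kDa), applies log10 intensity
    conversion and a sliding-window top-fraction noise filter, and computes
    composite correlation index (CCI) relatedness matrices from
    interval-wise Pearson correlations. Downstream stages provide
    Bray-Curtis principal coordinates analysis, single-linkage dendrograms
    of the mass profiles, a neighbor-joining 16S rRNA phylogeny with
    bootstrap supports, and a grouping-concordance report (per-species
    consistency, grouping-similarity fraction, Sankey edge table) comparing
    the dendrogram with the phylogeny. A seeded synthetic-data module
    generates hierarchically structured spectra (genus-conserved,
    species-specific, strain-variable peaks) and co-evolved 16S-like
    sequences so the whole analysis can be validated against known truth.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    ape,
    phangorn,
    vegan,
    cluster,
    mclust,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
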