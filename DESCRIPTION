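Package: comboscreen
Title: Analysis of Combinatorial Dual-Cas9 CRISPR Knockout Screens
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for pooled combinatorial CRISPR knockout screens that pair
    one S. pyogenes and one S. aureus Cas9 guide per construct. Converts raw
    construct read counts into log2 fold changes against a plasmid-pool
    reference, scores genetic interactions by per-anchor-sgRNA linear
    regression of combination fitness against partner single-knockout fitness
    with within-anchor residual z-scores aggregated to gene-pair scores, and
    classifies pairs as synergistic lethal, compensatory non-lethal, buffering
    or neutral. Includes replicate and Cas9-ortholog concordance QC, a
    generative simulator of dual-guide screens with known ground truth, and an
    end-to-end pipeline with reproducible run manifests.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    SummarizedExperiment,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    yaml,
    optparse
Config/testthat/edition: 3
biocViews: CRISPR, PooledScreens, FunctionalGenomics, QualityControl, Software
RoxygenNote: 7.3.3
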