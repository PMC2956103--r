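Package: tgxtools
Title: Gene Set Scoring and Network Inference for Toxicogenomics Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quality-weighted scoring of toxicogenomics (TGx) biomarker gene
    sets from microarray expression data, and inference of gene set- and
    phenotype-level association networks. Implements the expression
    ratio-based TGP1 score and the detection call-weighted D-score,
    shrinkage-regularized Gaussian graphical model (GGM) partial
    correlation estimation over gene-set score profiles and phenotype
    changing levels, edge selection (threshold, top-k, permutation FDR),
    and the standard presentation modes of the field: radar charts, time
    course heat maps, and score-colored supervised pathway networks.
    Includes seeded synthetic-data generators with planted ground truth
    for validating scoring and network recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    grid,
    tools,
    igraph,
    pheatmap,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    xml2
Config/testthat/edition: 3
RoxygenNote: 7.3.3
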