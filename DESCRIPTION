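Package: spermshape
Title: Sperm Nuclear Morphometry, Shape Clustering and Sex-Ratio Drive Statistics
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Outline-based morphometry of falciform (hook-shaped) sperm
    nuclei and the statistics used to study sex-ratio drive in mice carrying
    Y-chromosome long-arm deficiencies. Provides a parametric synthetic-data
    generator for sperm-head outlines with planted genotype and X/Y-bearing
    effects, rasterization to noisy micrograph-like images, segmentation and
    outline extraction, sliding-window interior-angle profiles anchored at
    the hook apex, landmark-aligned consensus shapes, t-SNE embedding and
    Ward clustering of angle profiles with per-cluster sex-chromosome
    composition, capture/recapture image matching by stage coordinates and
    structural similarity, and the proportion, rank-based and
    beta-regression tests applied to swim-up motility fractionation data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    tools,
    pracma,
    cluster,
    EBImage,
    tiff,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mclust,
    knitr,
    rmarkdown
Config/testthat/edition: 3
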