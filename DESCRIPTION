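Package: retort
Title: Retinal Vessel Tortuosity from Fundus Images
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Measures retinal blood-vessel tortuosity from colour fundus
    photographs. The pipeline segments vessels by ISODATA thresholding of the
    LAB b channel with morphological cleanup and multiscale vesselness
    enhancement, separates arteries from veins using colour-coded ground-truth
    label maps (red = artery, blue = vein, green = overlap), thins each class
    to a one-pixel skeleton, anchors vessel start points on the optic-disc
    boundary band, traces each vessel by breadth-first search over the
    8-connected skeleton graph, and reports arc-to-chord tortuosity per vessel
    together with per-image aggregates and artery-versus-vein comparison
    statistics (Shapiro-Wilk gate, Pearson/Spearman correlation, regression
    R-squared, Cohen's d, Mann-Whitney U, Wilcoxon signed-rank). A synthetic
    phantom generator with analytic arc-length ground truth makes every stage
    testable without external datasets.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    generics,
    grDevices,
    jsonlite,
    stats,
    tibble,
    tools,
    utils,
    yaml
Suggests:
    ggplot2,
    igraph,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
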