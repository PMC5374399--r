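Package: syncytrack
Title: Segmentation Post-Processing, Tracking and Quantification of Nuclei
    in 3D Time-Lapse Microscopy of Syncytial Embryos
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantitative analysis of cortical nuclei in 3D time-lapse
    fluorescence microscopy of syncytial embryos. Provides geometric primitives
    for nuclei represented as stacks of planar contours, a shape-split algorithm
    that separates under-segmented (touching) nuclei and rebuilds 3D objects by
    inter-plane overlap, composite segmentation layers, bilateral nearest-neighbour
    tracking with lineage editing and detection of divisions and mitotic
    chromosome collisions, and population statistics: convex-hull nuclear density,
    volume-to-hull ratio, two-phase nuclear growth regression, ploidy
    classification and per-cycle reporter-intensity changes. A synthetic
    syncytial-embryo generator produces ground-truth nuclear dynamics and renders
    them as noisy image stacks so that every pipeline stage can be benchmarked
    without microscope data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
Depends: R (>= 4.0)
Imports:
    grDevices,
    igraph,
    pracma,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    tiff,
    yaml,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
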