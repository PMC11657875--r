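Package: spinemorph
Title: Dendritic Spine Morphometry, Profile Clustering, and Dendrite Heterogeneity Statistics
Version: 0.1.0
Authors@R: person("Morphometry", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Skeleton-based width profiling of dendritic spines imaged in
    anisotropic 3D fluorescence stacks, ten quantitative shape descriptors
    (head and neck diameter, their ratio, length, areas, and width
    variability), Ward hierarchical clustering of 175-dimensional
    profile-plus-length feature vectors with Davies-Bouldin class-number
    selection, and the contingency-table and rank-test statistics used to
    assess whether spine classes are homogeneously distributed among
    dendrites. Includes plane-wise Wiener deconvolution with a 2D Lorentzian
    point spread function and a synthetic spine generator with known class
    ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    xml2
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
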