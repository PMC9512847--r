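Package: colonymorph
Title: Morphometric Trajectory Analysis of Laterally Confined Cell Colonies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Image-derived analysis of laterally confined fibroblast growth on
    rectangular micropatterns. Segments colonies and nuclei from 3D confocal
    stacks (Gaussian smoothing, Otsu thresholding, anisotropic Euclidean
    distance transform and seeded 3D watershed), computes colony- and
    nucleus-level morphometric features (volume, sphericity, bounding-ellipsoid
    elongation and flatness, Feret diameters, heterochromatin volume, Haralick
    grey-level co-occurrence textures), builds composite state indices (Colony
    Growth Index and Chromatin Reorganization Index) by PCA followed by linear
    discriminant analysis, infers diffusion-map pseudotime with three-branch
    detection and Nystrom projection of held-out colonies, quantifies alkaline
    phosphatase activity in brightfield images by colour deconvolution, and
    classifies colony proliferation from EdU labelling. Ships a synthetic
    colony time-course generator with planted ground truth so every stage can
    be validated end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    MASS,
    Rcpp,
    stats,
    utils,
    jsonlite,
    yaml,
    tiff,
    EBImage
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
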