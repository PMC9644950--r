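Package: bonevasc
Title: 3D Cortical Bone Vascular Microstructure and Growth Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies the vascular canal network of long-bone cortical bone
    from 3D micro-CT image stacks and relates it to skeletal growth. Provides
    segmentation of the mineralised cortex by minimum cross-entropy (Li)
    thresholding, morphological closing and size-based partition of pores into
    vascular canals and osteocyte lacunae; 3D histomorphometry (cortical
    porosity, sphere-fitting local thickness of canals and cortex, second
    moment of area of the mid-shaft annulus); skeleton-based canal orientation
    analysis with length-weighted laminar, longitudinal, radial and oblique
    indices; Gompertz growth-curve fitting with growth-rate curves, and beta
    regression with a logit link for proportion outcomes. A ground-truthed
    synthetic phantom generator emulating a mid-diaphyseal cortex makes the
    whole pipeline testable without external scan data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    igraph,
    jsonlite,
    minpack.lm,
    stats,
    graphics,
    grDevices,
    tiff,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    glmmTMB,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
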