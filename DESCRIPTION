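Package: plexbridge
Title: Panel-Bridging Integration of Standard Immunofluorescence via Virtual Labelling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Integrates multiple standard 4-plex immunofluorescence panels into one
    high-plexity single-cell dataset. Wells share label-free and anchoring fluorescence
    channels while each carries a single variable marker; one image-to-image
    virtual-labelling model (U-Net or conditional GAN with LSGAN + L1 loss) is trained
    per variable marker on its labelled wells and applied to all wells, bridging cell
    populations into a unified marker matrix. Includes a reproducible synthetic
    epithelial-mesenchymal dataset generator with ground truth, the image preprocessing
    chain, native seeded-watershed segmentation with CellProfiler-convention single-cell
    features (morphology, intensity, radial distribution, Haralick texture,
    colocalisation), image- and feature-level fidelity metrics (SSIM, Pearson
    correlations, Welch tests), treatment classification (PCA + SVM), manifold
    embedding, and principal-curve pseudotime with marker-dynamics curves.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    tiff,
    yaml,
    jsonlite,
    EBImage,
    e1071,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
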