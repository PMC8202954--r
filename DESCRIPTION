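Package: cryptflow
Title: Deep-Learning Morphometry of Intestinal Crypts in Colitis Histology
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: An end-to-end digital-pathology workflow for quantifying crypt
    injury and recovery in experimental colitis models. Provides supervised
    gland/mucosa segmentation of H&E-stained colon sections with a U-Net
    trained on randomly tiled, augmented annotation windows and applied at
    slide scale with the overlap-tile strategy; unsupervised latent
    representation of segmented crypts with a dual-stream convolutional
    autoencoder over centrally and peripherally sampled patch stacks,
    visualized by t-SNE; masked first-order and gray-level co-occurrence
    (Haralick) texture features, Canny edge density and nearest-neighbour
    morphometrics per crypt and per slide; and cohort statistics (Welch
    t-tests, Pearson correlation, PCA, z-scored hierarchical clustering).
    A built-in synthetic mucosa generator with exact ground truth emulates
    the naive / colitis / treated continuum so the whole pipeline can be
    exercised and tested without whole-slide images. The convolutional
    networks run on a compact CPU engine (im2col + BLAS) included in the
    package.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    tools,
    EBImage,
    png,
    tiff,
    jsonlite,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
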