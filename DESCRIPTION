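Package: fkmeans
Title: Fractal-Guided K-Means Segmentation of Left Atrial Fibrosis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Automatic segmentation of left atrial fibrosis from 3D
    late-gadolinium-enhancement MRI-like volumes. Implements Voronoi-based
    clipping of the mitral valve, pulmonary veins and left atrial appendage
    using differential box-counting fractal dimension and skeleton
    tortuosity features, followed by hierarchical fractal-penalized
    K-means++ clustering of the clipped atrial wall. Includes a synthetic
    phantom generator for end-to-end testing, 2D K-means and 3D
    region-growing baselines, and a full segmentation metric suite
    (Dice, precision, recall, ASSD, MSSD, Hausdorff distance, HD95,
    intraclass correlation).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    RNifti,
    EBImage,
    igraph,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
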