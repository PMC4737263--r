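Package: svdmap
Title: Spatial Probability Mapping of Cerebral Small Vessel Disease Lesions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A reproducible pipeline for comparing the spatial distribution of
    cerebral small vessel disease lesions: multispectral segmentation of white
    matter hyperintensities by red/green/blue fusion of two MRI sequences and
    minimum-variance colour quantization, semi-automatic lacune detection by
    intensity thresholding and morphometry, Mahalanobis-distance selection of
    a population-representative template subject, affine intensity-based
    registration of images and binary lesion masks into a common space,
    voxel-wise lesion probability-density maps with per-class denominators,
    region-of-interest quantification against a subcortical atlas, and
    Friedman rank-based comparison of regional lesion distributions. Includes
    a synthetic-cohort generator producing multi-sequence brain phantoms with
    ground-truth lesion masks, known affine misalignments and volumetric
    features, so that every stage is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    RNifti,
    igraph,
    jsonlite,
    yaml,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    EBImage,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
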