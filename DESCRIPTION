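Package: wmhpath
Title: Voxel-Wise MRI-Histopathology Correlation in Periventricular White Matter
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end analysis of the relation between FLAIR signal in
    periventricular white matter hyperintensities (WMH) and normal-appearing
    white matter (NAWM) and quantitative histopathology. Provides a synthetic
    phantom generator with planted intensity-to-pathology gradients, a compact
    CPU-trainable U-Net ensemble for four-class tissue segmentation, k-means
    sub-segmentation of white matter into ordered FLAIR-intensity segments,
    landmark-based 2D affine co-registration of MRI to histology, colour
    deconvolution of stained sections, polarized light imaging (PLI)
    retardance and fiber-dispersion quantification, aggregation into
    0.16 mm^2 analysis blocks with a 50% tissue-inclusion rule, and the
    group/ROI/segment statistics (covariate-adjusted ANOVA with Bonferroni
    correction, voxel-wise Pearson correlation) used to characterise
    myelin and axonal damage gradients.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    stats,
    utils,
    car,
    RNifti,
    tiff,
    png,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
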