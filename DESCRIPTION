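Package: csdce
Title: Temporal Regularizers for Compressed Sensing Dynamic
    Contrast-Enhanced MRI
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools to evaluate temporal sparsity-promoting regularizers for
    compressed sensing reconstruction of dynamic contrast-enhanced (DCE)
    MRI. Provides a digital breast-like DCE phantom with known Tofts-Kety
    pharmacokinetic ground truth, seeded Cartesian variable-density
    undersampling masks, FISTA-based constrained reconstruction with five
    temporal regularizers (temporal Fourier and Haar wavelet l1 penalties,
    temporal total variation, second-order temporal total generalized
    variation, and the nuclear norm of the Casorati matrix), voxelwise
    Tofts-Kety model fitting, and agreement metrics (signal-to-error ratio,
    concordance correlation, Bland-Altman, paired tests) over ensembles of
    sampling patterns.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    minpack.lm,
    stats,
    utils
Suggests:
    RNifti,
    jsonlite,
    png,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
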