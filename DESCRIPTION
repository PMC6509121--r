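Package: qmrcart
Title: Quantitative MRI-Informed Computational Modelling of Articular Cartilage
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Per-pixel quantitative MRI relaxometry (T1, T1rho, T2, T2*),
    conversion of relaxation-time maps into depth-resolved fluid, collagen and
    proteoglycan volume fractions via exponential calibrations and weighted
    rational depth profiles, an anisotropic fiber-reinforced hyperelastic
    constitutive model of cartilage with osmotic swelling, a layered
    equilibrium solver for confined compression, and inverse identification of
    a global material parameter set from multi-sample stress-strain data.
    Synthetic phantom generators make the whole pipeline testable without
    measured data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    minpack.lm,
    EBImage,
    RNifti,
    tiff,
    png,
    yaml,
    jsonlite,
    pracma,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
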