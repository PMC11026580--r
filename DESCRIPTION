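Package: igaflex
Title: Solution-Scattering Analysis of Antibody Fab-Fc Flexibility
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for studying the conformational flexibility of
    multidomain glycoproteins, in particular IgA2-class antibodies, with
    small-angle X-ray scattering (SAXS). Includes a coarse-grained
    builder for glycosylated antibody models with known ground truth,
    Debye-formula profile computation, model-free reductions (Guinier
    analysis, regularized indirect Fourier transform for the pair
    distribution function, dimensionless Kratky analysis, SEC-SAXS frame
    processing), rigid-body conformational sampling over hinge, tailpiece
    and glycan degrees of freedom, multistate ensemble fitting with
    Rg-distribution state counting, and auxiliary fits for 1:1 surface
    plasmon resonance kinetics and thermal-melt temperatures.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    bio3d,
    graphics,
    minpack.lm,
    pracma,
    signal,
    stats,
    utils,
    withr
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
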