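Package: fftumor
Title: Fractal-Fractional Dynamics of Tumor-Normal Cell Competition Under Radiotherapy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for a two-population competition model of healthy and
    malignant cells under continuous radiation, posed with a fractal-fractional
    derivative in the Atangana-Baleanu (Mittag-Leffler kernel) sense. Provides
    the special functions and fractal-fractional integral operators, the model
    right-hand sides with equilibria, reproduction-ratio thresholds, Jacobian
    and Matignon local-stability verdicts, Volterra-type Lyapunov diagnostics
    with first and second time derivatives, linear-growth and Lipschitz
    existence constants with brute-force verification, a two-step
    Lagrange-interpolation integrator for the fractal-fractional system with a
    classical adaptive oracle, patient presets, table regeneration with
    discrepancy reporting, and least-squares parameter fitting on synthetic
    observations.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    deSolve,
    minpack.lm,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
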