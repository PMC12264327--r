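Package: shadowconstancy
Title: Simulation and Analysis of Human Color Constancy in Cast Shadows
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Colorimetric pipeline for achromatic-setting experiments on color
    constancy in cast shadows. Provides spectral integration to cone
    excitations with synthetic Stockman-Sharpe-style 2-degree cone
    fundamentals, MacLeod-Boynton and CIE xy chromaticities, a display
    characterization model, a two-illuminant (sunlight plus skylight)
    cast-shadow scene generator with spectra synthesized to target
    chromaticities, a parametric partial-constancy observer simulator, and the
    vector-angle Brunswick constancy index with standard-deviation axis
    rescaling, aggregation, and the associated statistical tests (paired t,
    Welch t, two-way repeated-measures ANOVA).
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    ggplot2,
    rlang
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
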