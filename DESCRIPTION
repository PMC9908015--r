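Package: plasmonruler
Title: Tethered-Nanoparticle Plasmon-Ruler Aptasensor Simulation and Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis toolkit for plasmon-ruler aptasensors in
    which a gold nanoparticle is tethered to a gold film by a conformation-
    switching DNA aptamer. Provides composite worm-like-chain Monte Carlo
    sampling of the tether, inverse-Boltzmann potentials of mean force,
    overdamped Brownian dynamics of the particle height, a gap-dependent
    two-mode plasmon scattering model with red/green (RG) ratio readout,
    ensemble-mode spectral calibration with limit-of-detection bracketing,
    single-particle dark-field image analysis, Sauerbrey quantification of
    quartz crystal microbalance traces, and synthetic-data generators with
    ground truth for every input the pipeline consumes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    EBImage,
    generics,
    ggplot2,
    grDevices,
    graphics,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    tiff,
    png,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
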