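Package: ptashb
Title: Photothermal Angular-Scattering Hemoglobinometry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulation and analysis toolkit for photothermal
    angular-scattering (PTAS) hemoglobin sensing. Provides a physics-based
    simulator of modulated scattering-fringe image stacks, Fourier
    fringe-phase lock-in demodulation of stacks into a scalar sensor
    signal, Hill-equation calibration between sensor signal and hemoglobin
    concentration, CLSI-style detection-limit (LoB/LoD/LoQ) and precision
    summaries, Passing-Bablok and Bland-Altman method-comparison
    statistics, and WHO-cutoff anemia classification with diagnostic
    performance metrics. Includes stack readers/writers (multi-page TIFF,
    PNG sequence, raw binary) and a command-line front end for
    reproducible end-to-end runs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    png,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
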