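Package: merkelsim
Title: Simulation of Tactile Encoding in Merkel Cell-Neurite Complexes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Forward model of slowly adapting type I (SAI) tactile afferents.
    Converts ramp-and-hold skin indentation into interior compressive stress
    through a quasi-linear viscoelastic surrogate of skin mechanics, transforms
    stress into receptor current with a three-component generator function
    (rapidly, slowly, and ultra-slowly inactivating currents convolved with the
    stress derivative), and predicts spike trains with per-heminode leaky
    integrate-and-fire dynamics over a multi-cluster end organ. Includes
    instantaneous-firing-frequency analysis, exponential-decay fitting of
    electrophysiology-style traces, end-organ-level estimation of the free
    current-scaling parameters, genotype presets (wildtype and Atoh1 knockout),
    and parameter-sweep utilities.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
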