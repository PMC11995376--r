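Package: isolact
Title: Isomer-Group Thermodynamics and Dissolution of Alpha-Lactose Monohydrate
Version: 1.0.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Thermodynamically consistent activity coefficients for two sugar
    isomers in chemical equilibrium in water (two-suffix Margules excess model
    integrated through the Gibbs-Duhem relation), calibration of the Margules
    constant and of the mutarotation equilibrium constant from water-activity
    and isomer-ratio measurements, solid-liquid equilibrium of alpha-lactose
    monohydrate via its solubility product (including the solubility depression
    caused by beta-lactose or foreign sugars), and a coupled
    dissolution-mutarotation simulator that solves the crystal population
    balance by the method of characteristics. Tidyverse-native: data frames in,
    tibbles out, with broom-style tidy()/glance() methods and ggplot2
    autoplot() methods.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    deSolve,
    dplyr,
    generics,
    ggplot2,
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
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
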