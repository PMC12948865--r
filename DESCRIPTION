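Package: rhizotrace
Title: Tracer Mass-Balance Analysis of Root and Rhizodeposition Carbon
    from 13C Pulse Labelling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for 13CO2 pulse-labelling field experiments
    on plant-soil carbon fluxes. Converts delta-13C measurements to atom
    fractions and atom excess, computes excess-13C mass per compartment,
    corrects fine-root carbon for extraneous organic matter with a two-pool
    isotope mixing model, partitions soil excess 13C into net rhizodeposition
    carbon (percent and quantity of carbon derived from rhizodeposition),
    and derives carbon-allocation coefficients and root:shoot ratios.
    Includes a forward simulator of the labelled plot experiment with known
    ground truth for parameter-recovery studies, and a classifier of
    prokaryotic taxa into copiotrophic and oligotrophic lifestyles by rrn
    copy number.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    ggplot2,
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
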