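Package: chitokin
Title: Subsite Kinetic Modeling of Exolytic Chitooligosaccharide Hydrolysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for mapping the sugar-binding subsites of exo-acting
    beta-N-acetylglucosaminidases from product time courses. Enumerates the
    binding modes of a chitooligosaccharide chain on a signed subsite cleft,
    converts additive per-subsite binding free energies into association
    constants, integrates the rapid-equilibrium mass-action system describing
    sequential GlcNAc(n) degradation, and estimates subsite free energies by
    derivative-free direction-set (Powell) least squares against measured or
    synthetic HPLC-style time courses. Also provides Michaelis-Menten
    estimation from initial-rate data, catalytic-efficiency arithmetic, a
    reproducible synthetic-data generator, CSV/YAML interchange, and a small
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0)
VignetteBuilder: knitr
Config/testthat/edition: 3
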