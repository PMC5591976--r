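Package: kroghchemo
Title: Krogh-Cylinder Model of Vascularized Tumour Response to Continuous Chemotherapy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates the response of a vascularized tumour to continuously
    delivered chemotherapy in a Krogh-type cylinder geometry. A quasi-steady
    radial drug-diffusion equation with cellular uptake is coupled to an
    integro-differential cell-density equation in which the kill rate is
    proportional to the cumulative drug uptake and growth is exponential.
    The drug field is solved by second-order finite differences on an
    annulus at every time step and the cell density is advanced with
    classical fourth-order Runge-Kutta. Provides nondimensionalization of
    physical constants, the viable-mass-ratio observable, long-term regime
    classification, deterministic parameter sweeps, closed-form oracle
    solutions for verification, tidy accessors, and ggplot2 visualisations.
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
    jsonlite,
    purrr,
    rlang,
    tibble,
    tidyr
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
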