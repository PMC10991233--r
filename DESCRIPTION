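Package: carokin
Title: Kinetic Modeling of Growth and Beta-Carotene Accumulation in
    Dunaliella salina
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Dynamic kinetic model of microalgal biomass growth and
    beta-carotene accumulation under co-limitation by temperature, average
    light intensity, nitrate and inorganic carbon. Couples a Monod/Aiba
    growth rate law with a double-Arrhenius temperature response and a
    logistic-ceiling carotene accumulation ODE, integrates batch cultures
    with day/night photoperiod switching, and estimates parameters from
    single-factor rate curves and batch time courses via bounded
    least squares and an adaptive particle swarm optimizer with
    perturbation sensitivity analysis. Includes a synthetic-data
    generator for single-factor experiments and validation batches.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    jsonlite,
    minpack.lm,
    stats,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
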