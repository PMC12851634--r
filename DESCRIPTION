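Package: thermofish
Title: Individual-Level Temperature- and Resource-Dependent Fish Bioenergetics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Deterministic individual-level simulator of fish growth, body
    condition, survival and fecundity under seasonal temperature forcing and
    constant feeding levels. Physiological rates (food intake, maintenance
    metabolism) scale allometrically with body mass and are modulated by
    size-dependent thermal performance curves with size-specific optimum and
    lethal temperatures. Body mass is split into structural and reserve
    components with a condition-dependent allocation rule; surplus reserves
    above the juvenile condition ceiling are spawned annually as eggs. Ships
    parameterizations for five marine fish species (Atlantic cod, Atlantic
    herring, five-bearded rockling, European sprat, thinlip mullet) and two
    seasonal temperature regimes of the southern Wadden Sea (1980s, 2010s),
    plus tidy accessors, diagnostics and plotting.
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
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
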