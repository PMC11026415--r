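Package: capion
Title: Calcium-Phosphate Ion Association from Potentiometric Titrations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Solution-speciation thermodynamics for aqueous calcium
    orthophosphate. Solves the coupled mass-action equilibria for the three
    1:1 calcium-phosphate ion pairs ([CaH2PO4]+, [CaHPO4]0 and [CaPO4]-)
    with Davies activity corrections, fits the association constants K1-K3
    to multi-pH potentiometric titration curves by global least squares,
    derives standard Gibbs energies, enthalpies and entropies of ion pairing
    from two-temperature data, and draws ion-pair speciation diagrams across
    pH. Includes a seeded titration simulator emulating calcium ion-selective
    electrode protocols, including the premature phase-separation artifact at
    the dosing tip that inflates apparent binding, and a half-equivalence
    analysis for phosphoric-acid pKa determination.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    generics,
    rlang,
    readr,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
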