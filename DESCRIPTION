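Package: spindlesim
Title: Mechanochemical Simulation of Kinetochore Capture by Spindle Microtubules
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale simulator of the search-and-capture phase of mitotic
    spindle assembly. Couples a lattice reaction-diffusion master equation
    (RDME) engine -- next-subvolume-method sampling of biochemical reactions
    and multi-particle lattice diffusion of enzymes -- to an overdamped
    Langevin bead-spring mechanics engine for centrosomes, elastic
    microtubules with dynamic instability, kinetochore pairs with an
    Ndc80-bearing corona, and chromosome arms. Microtubule plus-ends attach to
    kinetochores through elastic Ndc80 linkers whose phosphorylation state,
    set by Aurora kinase and phosphatase kinetics, controls detachment rates.
    Includes attachment-error classification (amphitelic, merotelic,
    monotelic, syntelic), spindle geometry readouts, diffusion-coefficient
    estimators, and a closed-form verification benchmark suite.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
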