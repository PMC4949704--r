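Package: ltcsr
Title: Largest Thermodynamically Consistent Sets of Elementary Flux Modes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Enumerates elementary flux modes (EFMs) of stoichiometric
    metabolic networks, tests their thermodynamic feasibility against
    metabolite concentration bounds and Gibbs formation energies, and
    computes largest thermodynamically consistent sets (LTCSs): maximal
    sets of feasible EFMs that can be jointly active under a single
    metabolite concentration vector.  LTCSs are found with a mixed-integer
    linear program using big-M indicator constraints and enumerated by
    successive exclusion; the resulting sets can be screened with yield
    thresholds, reaction direction data, and Venn-segment support
    statistics down to the biologically relevant candidates.  Steady-state
    fluxes can be decomposed conformally into the EFMs of one set.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    xml2
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
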