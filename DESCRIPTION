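Package: folatekin
Title: Inhibition Kinetics and Quantitative Cell-Delivery Analysis for
    Folate-Peptide Conjugates
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis toolkit for folate-peptide conjugate assay data:
    a coupled-equilibrium model of human thymidylate synthase inhibition
    with double-reciprocal (Lineweaver-Burk) fitting, mixed-vs-competitive
    classification and apparent-to-microscopic inhibition-constant
    inference; subcellular compartment concentration quantification with
    charge-state/neutral-mass arithmetic and fluorometric back-calculation;
    first-order biostability kinetics; radioligand competitive-binding
    ratio and free-energy analysis; and drug-combination synergism-quotient
    scoring with hierarchical clustering. Includes a synthetic-data
    generator emulating the assay designs so every stage is testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    ape
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
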