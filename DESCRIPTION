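Package: idplink
Title: Linking Disordered-Protein Monomer Conformation to Aggregation Propensity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline connecting the solution conformation of
    intrinsically disordered protein monomers (SAXS radius of gyration,
    Flory exponent from a polymer molecular form factor, second virial
    coefficient from SEC-SAXS, ion-mobility collision cross sections) to
    their aggregation propensity (ThT kinetic halftimes) and
    liquid-liquid phase-separation saturation concentration. Includes
    SAXS frame quality control and buffer subtraction, a window-scanned
    Guinier histogram estimator, sigmoid kinetics fitting, a turbidity
    t-test ladder for the saturation concentration, step-field drift-tube
    mobility regression with Mason-Schamp conversion, cross-condition
    regressions with an elbow-method cluster check, and a synthetic-data
    generator (including a pivot-algorithm self-avoiding-walk sampler)
    so the whole chain is testable without beamline or plate-reader data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    minpack.lm,
    Rcpp,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
NeedsCompilation: yes
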