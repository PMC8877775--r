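Package: qce
Title: Quantum Cluster Equilibrium Thermodynamics with Hindered-Rotor
    Corrections
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Statistical-thermodynamic engine for the quantum cluster
    equilibrium (QCE) model of associated fluids. A fluid is described as a
    mixture of quantum-chemically characterized molecular clusters in
    chemical equilibrium; canonical partition functions (particle-in-a-box
    translation, rigid rotor, harmonic oscillator with an optional modified
    rigid-rotor-harmonic-oscillator treatment of low-frequency modes as
    hindered rotations) yield populations, phase volumes, isobars,
    vapor-liquid transition temperatures, densities, entropies, vaporization
    enthalpies via Clausius-Clapeyron analysis, and ionic products from
    ion-pair cluster populations. Includes a downhill-simplex optimizer for
    the mean-field and excluded-volume parameters and deterministic
    synthetic cluster-set generators for testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
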