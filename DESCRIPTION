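Package: unfoldkit
Title: Equilibrium Unfolding Thermodynamics and Constraint-Network Rigidity
    Analysis of Protein Stability
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for the biophysical characterization of protein stability:
    fitting of pH titrations (Hill model), chemical denaturation curves
    (linear extrapolation model), thermal denaturation curves
    (Gibbs-Helmholtz), thermal-shift (differential scanning fluorimetry)
    traces and two-transition differential scanning calorimetry thermograms,
    with equilibrium state-population analysis; plus a graph-rigidity
    simulated thermal unfolding built on a body-and-bar constraint network
    and a (6,6) pebble game, reporting global (floppy mode density, cluster
    configuration entropy, rigidity order parameter) and per-residue
    (percolation, rigidity, weak-spot frequency) flexibility indexes over
    single networks and fuzzy ensembles. A seeded synthetic-data module
    generates every input the pipeline consumes, including ideal alpha-helix
    structure fixtures.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    minpack.lm,
    jsonlite,
    bio3d
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
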