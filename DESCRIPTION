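Package: hillcube
Title: Semi-Quantitative Simulation of Boolean Signaling Networks via
    Normalized HillCube Dynamics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for representing Boolean models of cell signaling as
    sum-of-products logic, simulating them discretely (synchronous updates,
    exhaustive attractor search) and continuously (BooleCube multilinear
    interpolation composed with normalized Hill functions, integrated as
    ordinary differential equations), and analysing them structurally
    (signed interaction graphs, strongly connected components, feedback-loop
    enumeration and per-node loop participation). Includes an in silico
    perturbation pipeline for knockout/knockin panels modeled on primary
    immunodeficiencies of B-cell receptor signaling, SBML-qual and rule-text
    model I/O, and a seeded synthetic-network generator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
Depends:
    R (>= 4.1)
Imports:
    deSolve,
    igraph,
    jsonlite,
    stats,
    tools,
    utils,
    xml2
Suggests:
    knitr,
    rmarkdown,
    testthat (>= 3.0.0)
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
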