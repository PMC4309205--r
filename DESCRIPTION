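Package: logimc
Title: Multivalued Logical Models, Attractors, and Action-Restricted Model
    Checking
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Author: Package Author [aut, cre]
Maintainer: Package Author <author@example.org>
Description: Definition and analysis of multivalued logical models of
    regulatory and signaling networks in the Thomas formalism: validation and
    perturbation of logical regulatory graphs, interaction and circuit
    functionality analysis, asynchronous and synchronous state transition
    graphs with attractor identification via terminal strongly connected
    components, stable-state enumeration across all input conditions without
    building the state transition graph, model reduction by component
    substitution preserving stable states, action-restricted CTL (ARCTL)
    model checking over input-labeled transition systems, and synthesis of
    reprograming graphs connecting phenotype patterns under environmental
    conditions. Models are read and written in SBML-qual and a plain-text
    multivalued rule format; a command-line interface exposes the pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    xml2
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
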