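Package: escrtsim
Title: Coarse-Grained Simulation of ESCRT-III Filament-Driven Membrane Remodelling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A particle-based coarse-grained model of ESCRT-III membrane
    remodelling. Chiral bead-spring filaments built from three-bead units are
    adsorbed on a solvent-free, one-particle-thick fluid membrane and evolved
    with Langevin dynamics. The target geometry of a filament can be switched
    between a flat ring and a tilted (helical) state, which drives directional
    membrane buckling (cones and tubules of either sign) and, combined with a
    membrane-bound cargo, vesicle scission by repeated geometry switching.
    Includes builders for filament spirals, membrane patches and cargo systems,
    a compiled Langevin engine with neighbour lists and a zero-tension lateral
    barostat, scripted protocols reproducing the model's reference scenarios,
    and analysis tools (deformation depth and shape classification, persistence
    length, membrane mechanics, scission detection).
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    igraph,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
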