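Package: capouch
Title: Multicellular Calcium Signaling Simulation in an Epithelial Pouch
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates intercellular calcium (Ca2+) signaling in the
    Drosophila wing imaginal disc pouch. Single-cell IP3/Ca2+/IP3-receptor
    kinetics are coupled across a synthetic Voronoi epithelium through gap
    junctions, reproducing the four observed classes of spatiotemporal
    activity (single-cell spikes, intercellular transients, intercellular
    waves, and global fluttering). Includes a tissue-geometry generator
    (Voronoi tessellation with Lloyd relaxation), numerical Hopf-bifurcation
    analysis of the single-cell model, scenario runners for gap-junction
    block and developmental scaling laws, parameter sensitivity sweeps, and
    automated quantification of trajectories (spike detection, frequency,
    width at half maximum, kymographs, pattern classification).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    igraph,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
NeedsCompilation: yes
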