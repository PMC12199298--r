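Package: qowire
Title: Hydrogen-Bond Networks, Proton Wires and Torsional Landscapes of the
    Cytochrome bc1 Qo Site
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis toolkit for the quinol-oxidation (Qo) site of
    cytochrome bc1: side-chain conformer classification and torsional-mode
    surveys over experimental structure ensembles, per-frame hydrogen-bond and
    water-bridge contact statistics (occupancy, lifetimes, hydration counts)
    on molecular-dynamics trajectories, free-energy profiles from plain or
    well-tempered metadynamics samples with bias-removal reweighting and
    replica averaging, enumeration of donor-to-release proton wires on a
    contact graph under a two-water-bridge rule, and multiple-sequence-
    alignment conservation tables. Synthetic generators (Boltzmann and
    well-tempered samplers, telegraph contact processes, planted structure
    ensembles and alignments) make every stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    bio3d,
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    igraph,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
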