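Package: pepcation
Title: Conformer Ensembles of Amino Acids and Dipeptides Bound to Divalent Cations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing conformer ensembles of the twenty proteinogenic
    amino acids and their capped dipeptide forms, alone and in complex with the
    divalent cations Ca, Ba, Sr, Cd, Pb and Hg. Provides readers and writers for
    multi-frame extended-XYZ conformer files, backbone torsion and hydrogen-bond
    geometry, classification of conformers into backbone structure types
    (type I/II, zwitterionic, charge-solvated, salt-bridge, C5, C7, cation-closed
    iC7), conformational energy hierarchies, cation binding energies and
    cross-ion trend statistics, coordination-shell and cation-oxygen distance
    diagnostics, a packaged ion reference table (Shannon radii, hydration
    enthalpies, chloride-salt LD50) with toxicity-trend correlation, and a
    seeded generator of labelled synthetic conformer ensembles driven by a toy
    electrostatic energy model and a torsional basin-hopping search.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    jsonlite,
    yaml,
    igraph,
    stats,
    graphics,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
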