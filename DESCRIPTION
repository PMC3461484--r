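Package: amberconv
Title: AMBER Small-Molecule Topology Conversion with Energy Verification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Reads AMBER-family molecular topology, parameter and coordinate
    files for small molecules (prmtop, inpcrd, Tripos MOL2, frcmod/parm-dat),
    converts functional forms, units and conventions, and writes all-atom
    topologies for GROMACS, CNS and CHARMM.  Proper and improper dihedrals are
    kept in the AMBER periodic (Fourier) form when targeting GROMACS, with an
    optional exact Ryckaert-Bellemans mapping; 1-4 pair lists, exclusions and
    truncated-octahedron box vectors are generated from first principles.  A
    built-in vacuum single-point energy evaluator certifies that every
    conversion preserves the potential energy term by term.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    igraph,
    jsonlite,
    optparse
Config/testthat/edition: 3
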