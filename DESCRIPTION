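Package: channelmcm
Title: Internal-Coordinate Monte Carlo Minimization for Ion-Channel State Modelling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Torsion-space (internal generalized coordinate) molecular modelling of
    voltage-gated ion channels and their disease mutants. Provides a minimal
    united-atom amino-acid topology with forward kinematics, a Lennard-Jones plus
    distance-dependent-dielectric Coulomb energy function with residue-pair
    decomposition, flat-bottom parabolic restraints (alpha-carbon pins, distance
    and torsion windows, helical hydrogen-bond restraints), a Monte Carlo
    minimization engine with a steered driver that walks restraint anchors between
    conformational states, pipeline stages for homology threading, open/closed
    state transformation and double-shell mutant sampling, residue contact-energy
    maps with interaction-type classification, Kabsch superposition, a universal
    P-loop residue nomenclature, and a deterministic synthetic toy-channel
    generator so that every stage runs at desk scale without external structures.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    bio3d,
    seqinr,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
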