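Package: quadval
Title: Validation of Quadruplex-Duplex MD Ensembles Against NMR Observables
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools to validate molecular-dynamics conformational ensembles of
    quadruplex-duplex nucleic acids against solution-NMR observables. Provides
    NOE distance back-calculation with r^-6 ensemble averaging and violation
    accounting, hydrogen-bond distance/angle persistence analysis, backbone
    torsion occupancy matrices with NMR-bundle overlays, element-wise RMSD and
    RMSF profiles, ion-atmosphere radial and spatial distribution functions
    with bulk-shell normalization, channel-cation occupancy classification with
    occupancy-based binding free energies, and duplex-focused hierarchical
    clustering with representativeness reporting. A synthetic-data module
    generates idealized tetrad stacks, duplex stems, Gaussian-fluctuating
    trajectories, scripted ion-entry events, and self-consistent restraint
    tables so every analysis stage is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    bio3d,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
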