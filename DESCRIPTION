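Package: anxmem
Title: Orientation Scanning and Interaction Analysis of Peripheral
    Membrane Proteins with Ca2+-Mediated Lipid Binding
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Builds and analyses protein-bilayer-Ca2+ systems for
    peripheral membrane proteins such as annexin A2. Provides systematic
    generation of protein orientations above a bilayer (principal-axis
    pre-alignment, X/Y rotation grids, minimal-distance Z placement,
    interfacial Ca2+ seeding), a simplified cutoff Coulomb plus
    Lennard-Jones interaction model with bound-ion classification and
    binding-enthalpy decomposition, per-residue contact and energy
    profiles with crystal-site comparison, Z-axis-constrained rotational
    RMSD, leaflet-resolved curvature (P-atom z-shift) maps with
    curvature-energy correlations, deuterium order parameter (S_CD)
    analysis, and a seeded synthetic-system and pseudo-trajectory
    generator with generator-side ground truth for parameter-recovery
    validation. Reads and writes PDB and GRO coordinate files.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
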