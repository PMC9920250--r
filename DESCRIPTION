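Package: qmetad
Title: Well-Tempered Metadynamics with a Self-Consistent-Charge
    Tight-Binding Engine
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A desk-scale stack for quantum-mechanically driven enhanced
    sampling of molecular conformations. Provides a third-order
    self-consistent-charge density-functional tight-binding (DFTB3) energy
    engine fed by Slater-Koster parameter tables, a from-scratch
    divide-and-conquer generalized symmetric eigensolver, NVT molecular
    dynamics with a Nose-Hoover thermostat, a well-tempered metadynamics
    driver with PLUMED-dialect HILLS/COLVAR input and output, and
    free-energy-surface analysis including internal-energy and entropy
    decomposition, basin free-energy differences and nudged-elastic-band
    transition paths. Synthetic Slater-Koster fixtures and analytic toy
    potentials make every component testable without external parameter
    downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, graphics, tools
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
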