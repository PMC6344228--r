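Package: cdkstates
Title: Comparative Conformational and Binding-Thermodynamic Analysis of
    Cyclin-Free and Cyclin-Bound CDK1/CDK2
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to compare cyclin-free and cyclin-bound states of the
    cell-cycle kinases CDK1 and CDK2. Structural metrics include an
    inter-lobe atomic contact census at a distance cutoff, assembly
    assessment of the regulatory (R) and catalytic (C) hydrophobic spines,
    Kabsch least-squares superposition RMSD with sequence-based C-alpha
    pairing, and a P-loop tyrosine conformation classifier (tucked-in
    versus popped-out). Binding thermodynamics cover a one-set-of-sites
    isothermal titration calorimetry (ITC) forward model and fit,
    thermodynamic signature decomposition (dG = dH - TdS), Boltzmann
    thermal-melt fitting with melting-temperature shifts, steady-state
    surface plasmon resonance affinity fits, logistic IC50 fits, and
    fold-selectivity tables. A seeded synthetic-data module generates
    every input the pipeline consumes, so all analyses run without
    downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    bio3d,
    Biostrings,
    minpack.lm,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
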