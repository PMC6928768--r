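Package: capsidhot
Title: Conservation-Based Hot-Spot Prediction and Binding Free-Energy
    Analysis for Icosahedral Viral Capsids
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools to predict protein-protein interface hot spots in
    icosahedral viral capsids from structural conservation, and to
    validate them thermodynamically. The prediction pipeline detects
    interface residues between capsid subunits generated by the 60-fold
    icosahedral rotation group, intersects them with sequence
    conservation from a multiple sequence alignment and with
    quaternary-structure conservation from angular (phi-psi) capsid
    maps aligned across a virus family. The thermodynamic half turns
    umbrella-sampling window time series into an unbiased potential of
    mean force via the Weighted Histogram Analysis Method (WHAM),
    extracts the dimer binding free energy as the global PMF minimum
    referenced to large subunit separation, and computes mutation-induced
    binding free-energy changes with bootstrap errors. Includes seeded
    synthetic generators (toy capsid families with planted conservation
    and exact Boltzmann samplers over known 1D potentials) used as test
    oracles, plus a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    bio3d,
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    withr,
    yaml,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
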