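Package: photocarrier
Title: Analysis of Photolipid-Regulated Carrier-Mediated Ion Transport
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantitative analysis of carrier-mediated ion transport
    across planar lipid bilayers under optical control by azobenzene
    photolipids. Provides seeded generators for synthetic voltage-clamp sweep
    sets, hydrophobic-anion redistribution transients and capacitance-voltage
    curves; epoch-averaged current-voltage reduction with supralinear,
    weighted-linear, mono- and global bi-exponential fitting; boundary-potential
    extraction from capacitance-voltage parabolas with surface-potential
    decomposition; an electrostatic/thermodynamic barrier calculator (Born and
    dipole energies, dielectric rescaling, weak-acid speciation, Nernst and
    Goldman-Hodgkin-Katz potentials); and a mechanistic four-step mobile-carrier
    cycle model with closed-form steady-state currents.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    jsonlite,
    minpack.lm,
    signal,
    stats,
    tibble,
    utils,
    withr
Suggests:
    deSolve,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
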