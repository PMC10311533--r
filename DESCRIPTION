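Package: lnshift
Title: Pseudocontact Shift Dynamics of C3-Symmetric Lanthanide Complexes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for the geometric and magnetic dynamics of
    tricapped C3-symmetric lanthanide(III) complexes in solution. Reads
    multi-frame XYZ trajectories, constructs the instantaneous pseudo-C3
    axis and donor-metal-axis angle time series, represents and decomposes
    magnetic susceptibility tensors, and computes pseudocontact NMR shifts
    both from full susceptibility tensors (point-dipole model) and from
    Bleaney's axial crystal-field approximation. A desk-scale crystal-field
    surrogate (Stevens operators, point-charge model, Van Vleck
    susceptibility) and a stochastic trajectory generator make every stage
    of the pipeline testable without ab initio molecular dynamics or
    multireference electronic-structure calculations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    pracma,
    stats,
    tools,
    utils,
    yaml
Suggests:
    bio3d,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
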