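Package: hopcrystal
Title: Hopping Charge-Transport Analysis for Molecular Crystals
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Pipeline for estimating hole and electron mobilities in
    molecular organic semiconductor crystals within the Marcus hopping
    picture. Reads crystal structures from CIF, expands symmetry,
    reassembles whole molecules across periodic boundaries and enumerates
    symmetry-unique neighbor dimers; computes frontier-orbital transfer
    integrals by dimer projection (DIPRO) with overlap correction;
    evaluates inner-sphere reorganization energies by the four-point
    adiabatic-potential scheme and decomposes them into normal-mode
    contributions (Huang-Rhys factors) with a Raman intensity proxy
    comparison; assembles Marcus hop rates into a diffusion tensor and
    converts it to isotropic mobility via the Einstein-Smoluchowski
    relation. Includes a tight-binding toy electronic-structure backend,
    a plain-text adapter for externally computed matrices, synthetic
    crystal and hop-network generators, a distance-based intermolecular
    contact classifier, and a kinetic Monte Carlo random-walk oracle for
    validating the analytic diffusion summation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
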