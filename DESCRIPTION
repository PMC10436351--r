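Package: iscatsim
Title: First-Principles Simulation of Mass Photometry Experiments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates interferometric scattering based mass photometry from
    first principles: Fourier-optics image formation of single biomolecules at
    a glass-water interface with a back-focal-plane attenuation mask,
    Rayleigh-sphere and coupled-dipole polarizability-tensor scatterer models,
    correlated cover-glass roughness and its speckle background, synthetic
    landing-assay movies with shot noise, the ratiometric detection, PSF
    fitting and mass-calibration pipeline, and closed-form photon-budget
    theory for signal-to-noise ratio, detection limit and mass resolution.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    tiff,
    bio3d
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
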