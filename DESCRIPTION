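Package: aptmd
Title: Molecular Dynamics in Homogeneous Electric Fields via Atomic Polar Tensors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A perturbative scheme for molecular dynamics in homogeneous
    external electric fields. Zero-field forces come from any interatomic
    potential; the field-induced force on each atom is the contraction of its
    atomic polar tensor (Born effective charge tensor) with the field vector,
    so the field response can be modelled by a tensor regressor trained
    exclusively at zero field. Includes analytic toy potentials with exactly
    known polar tensors, a finite-difference dipole-derivative oracle,
    acoustic sum-rule projection, a linear E(3)-equivariant local tensor
    regressor, velocity-Verlet propagation with a canonical-sampling
    velocity-rescaling (CSVR) thermostat, piecewise-constant field protocols,
    and the dielectric observable stack: anchored dipole integration,
    polarization, static dielectric constant by field sweep and by zero-field
    fluctuations, infrared spectra from the dipole-velocity autocorrelation,
    and orientational relaxation analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    minpack.lm,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
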