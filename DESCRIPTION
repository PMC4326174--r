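Package: AllosTraj
Title: Trajectory Analysis of Interdomain Allostery and Forced Unbinding
    in Modular Adhesion Receptors
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Quantifies conformational allostery and forced-dissociation
    behaviour of multi-domain adhesion receptors (the P-selectin lectin /
    EGF / consensus-repeat architecture and its PSGL-1 ligand) from
    molecular-dynamics trajectories. Provides interdomain hinge-angle
    metrics built on optimal rigid-body superposition, loop RMSD series
    against labelled reference conformations with threshold-based state
    classification, group-group van der Waals and electrostatic
    interaction energies under a smooth switched cutoff, and
    steered-dynamics unbinding observables (molecular extension, complex
    separation, dissociation-time detection by the zero-energy
    criterion, force-profile features). A deterministic synthetic
    rigid-body trajectory generator with machine-readable ground truth
    allows the whole pipeline to be exercised and validated at desk
    scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    bio3d,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
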