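Package: mocomodl
Title: Non-Rigid Motion-Corrected Unrolled Reconstruction for Accelerated 3D Whole-Heart MRI
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Implements a motion-corrected model-based deep-learning (MoCo-MoDL)
    reconstruction pipeline for accelerated free-breathing 3D whole-heart MRI:
    variable-density spiral-profile Cartesian (CASPR-style) trajectory generation
    with elliptical shutter and density-preserving retrospective undersampling,
    soft-gated respiratory binning with image-navigator translational correction,
    a multi-coil motion-corrected encoding operator with conjugate-gradient data
    consistency, diffeomorphic velocity-field motion estimation integrated by
    scaling and squaring, an unrolled alternation of data-consistency solves and
    a learned residual denoiser, end-to-end training of both networks, and a
    deforming numerical thorax phantom for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
NeedsCompilation: yes
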