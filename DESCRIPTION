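Package: cardiofiber
Title: Reconstruction of Dense Left-Ventricular Myofiber Fields from Sparse Cardiac Diffusion Tensor Imaging
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to reconstruct dense three-dimensional left-ventricular
    myofiber and sheetlet orientation fields from sparse short-axis cardiac
    diffusion tensor imaging (cDTI) data.  Provides a synthetic truncated
    ellipsoidal left-ventricle generator with ground-truth microstructure and
    simulated diffusion-weighted acquisitions; shape-adapted ventricular
    coordinates (transmural, circumferential, longitudinal) from
    Laplace-Dirichlet problems on labeled tetrahedral meshes with
    re-orthogonalized local frames; Moore-Penrose diffusion tensor fitting
    with sign-fixed principal fiber extraction; four sparse-to-dense fiber
    interpolation methods of increasing smoothness (log-Euclidean anisotropic
    kernel tensor interpolation, proper generalized decomposition and gappy
    proper orthogonal decomposition low-rank models, and a rule-based linear
    angle method); helix, transverse and sheetlet (E2A) angle conventions with
    sheet construction to a target E2A; leave-one-slice-out interpolation
    error evaluation; and material-point evaluation of the orthotropic
    Holzapfel-Ogden passive law and a Guccione-type time-varying elastance
    active tension model.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    xml2,
    yaml,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
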