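Package: seg2fem
Title: Automated Finite-Element Models of Vertebrae and Intervertebral
    Discs from Labeled MRI Volumes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Converts labeled spine MRI segmentation volumes (vertebrae and
    intervertebral discs) into simulation-ready tetrahedral finite-element
    models. Provides voxel mask cleanup, marching-tetrahedra surface
    extraction, anatomically constrained smoothing with shared-node contact
    surfaces between adjacent bodies, constrained tetrahedral volume meshing
    with quadratic (10-node) elements, ABAQUS-dialect .inp model export with
    node sets, kinematic coupling, loads and boundary conditions, a static
    linear-elastic solver with von Mises stress recovery, and cohort-level
    mesh-quality reporting. Includes a synthetic voxel phantom generator with
    MRI-like anisotropic resolution and injectable segmentation defects so the
    whole pipeline can be exercised without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
SystemRequirements: Python (>= 3.8) with NumPy and SciPy on the PATH
    (Delaunay kernel used by the volume mesher)
Imports:
    Rcpp,
    Matrix,
    igraph,
    RNifti,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
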