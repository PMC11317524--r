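Package: neuromesh
Title: Watertight Surface Mesh Synthesis from Neuronal Morphologies
Version: 0.9.0
Authors@R:
    person("Neuromesh", "Developers", email = "neuromesh@example.org",
           role = c("aut", "cre"))
Description: Converts point-and-diameter neuronal morphology skeletons
    (SWC format) into geometrically realistic, watertight triangular
    surface manifolds suitable for tetrahedralization and
    reaction-diffusion simulation. The pipeline builds overlapping proxy
    meshes for arbors (swept tubes along node-to-leaf paths or
    articulated sections), grows a soft-body soma with mass-spring
    dynamics, integrates parametric dendritic spine meshes, welds
    everything by solid voxelization at a feature-derived resolution
    followed by topology-consistent polygonization, and finishes with
    adaptive quadric coarsening, volume-compensated smoothing and an
    iterative watertightness-verification repair loop. Includes mesh
    quality metrics (Verdict-style triangle statistics), watertightness
    certification, STL/OBJ/PLY export and a synthetic morphology
    generator for fully self-contained testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    igraph,
    jsonlite,
    withr,
    stats,
    utils,
    grDevices,
    graphics
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
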