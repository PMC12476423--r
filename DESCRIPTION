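Package: octodeform
Title: Octree Deformable Organ Models with Batched Trilinear Deformation Mapping
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Hybrid deformable-organ modelling for real-time surgical
    simulation. Builds an adaptive octree cube lattice over a closed organ
    surface mesh, animates the lattice with position-based dynamics using
    per-cube shape-matching constraints and tray-plane collision, and maps
    the lattice deformation back onto the high-resolution render mesh by
    trilinear interpolation of the eight deformed cube corners - either
    vertex-by-vertex or through a batched per-cube path that mirrors a
    vertex-shader implementation. Includes mesh readers and writers for
    OBJ, PLY and STL, a synthetic organ-mesh generator, mesh partitioning
    into per-cube pieces, and a linear timing model that fits per-frame
    mapping cost against vertex and surface-cube counts and predicts the
    crossover point at which the batched path outruns the per-vertex path.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
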