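Package: polylat
Title: Image-Based Polygonal Lattice Models for Plane-Strain Tissue Mechanics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Finite-deformation mechanics of heterogeneous biological materials
    on polygonal lattices built directly from segmented images. Segmented label
    images are turned into conforming meshes that keep a uniform square grid
    inside homogeneous phases and split boundary cells into convex cut-cell
    polygon pairs. On each convex polygon, Wachspress generalized barycentric
    coordinates yield lattice spring constants whose quadratic energy, together
    with an element-wise area (volume) term, reproduces the nearly
    incompressible neo-Hookean plane-strain energy. Quasi-static equilibria are
    found by incremental Newton energy minimization with line search. Includes
    a Lloyd-relaxed centroidal Voronoi mesher for homogeneous benchmark
    domains, programmatic benchmark fixtures (circular inclusions, sinusoidal
    bilayer, multi-inclusion composites, a femur-like blob), convergence
    studies, and legacy-VTK/JSON export.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    grDevices,
    jsonlite,
    png,
    stats
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
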