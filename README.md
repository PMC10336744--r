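# polylat

Image-based polygonal lattice mechanics for heterogeneous soft materials in
2D plane strain.

Biological materials — bone sections, tissue with tumors or inclusions,
engineered biomimetic composites — are multiphase solids whose geometry
usually arrives as a segmented image. Meshing such geometry for nonlinear,
nearly incompressible mechanics is the expensive step: conforming
triangulations discard the image's natural uniform grid, while voxel meshes
staircase the interfaces. `polylat` keeps the uniform square grid inside
each homogeneous phase and handles boundaries by splitting only the grid
cells crossed by an interface into pairs of convex polygons (a triangle and
a pentagon, a triangle and a quadrilateral, two quadrilaterals, or two
triangles), producing a conforming polygonal mesh directly from the image.

## The model

On every convex polygonal element, Wachspress generalized barycentric
coordinates turn the neo-Hookean plane-strain energy

$$ W(F) = \tfrac{\mu}{2}(I_1 - 2) - \mu(J - 1) + \tfrac{K}{2}(J - 1)^2,
\qquad I_1 = F\!:\!F,\quad J = \det F $$

into two element-level ingredients:

* a **lattice of springs** between every vertex pair, with constants
  $k_{ab} = -\mu \int \nabla\varphi_a \cdot \nabla\varphi_b\, dA$ derived
  from the shape-function gradients (edge springs $\mu/6$ and diagonal
  springs $\mu/3$ on a square), which reproduces the $I_1$ term exactly for
  affine deformations; and
* an **area penalty** $U_J = -\mu (A - A_0) + \tfrac{K}{2}(A - A_0)^2/A_0$
  per element — in plane strain the volume ratio is the area ratio — whose
  single $J$ per polygon avoids volumetric locking at large $K/\mu$.

Quasi-static equilibria are found by load-stepped Newton minimization of
the total potential energy (linear predictor per step, modified-Newton
shifts for indefinite tangents, backtracking line search that keeps all
element areas positive). A Lloyd-relaxed centroidal Voronoi mesher covers
the fully polygonal homogeneous benchmarks (uniaxial tension, Cook
membrane), and all benchmark fixtures — circular inclusions, a sinusoidal
bilayer, a 16-inclusion composite, a femur-like synthetic blob — are
generated in code. Units: mm, kPa, mN, per unit out-of-plane thickness.

See `vignette("polygonal-lattice-model")` for the full account of the
discretization, the solver, and the verification strategy.

## Worked example

A stiff circular inclusion ($\mu = 10$, $K = 1000$ kPa) in a soft matrix
($\mu = 1$, $K = 100$ kPa), stretched to twice its height:

```r
library(polylat)

# segmented image of a stiff circular inclusion in a soft matrix
img <- make_circle_inclusion_image()   # 20 x 10 mm, r = 2.5 mm, 10 px/mm
img
#> <label_image> 200 x 100 px at 0.1 mm/px, labels: 0, 1

# conforming polygonal mesh: 1 mm background squares, cut cells at the interface
mesh <- build_mesh_from_image(img, h = 1, phase_labels = c(0L, 1L))
mesh
#> <poly_mesh> 251 nodes, 220 elements (n = 3..5), regions: 0, 1

# nearly incompressible neo-Hookean phases (kPa)
mats <- list(`0` = material(1, 100), `1` = material(10, 1000))

# stretch the sample to twice its height
sol <- solve_static(mesh, mats,
                    list(bc_dirichlet("y==min", c(0, 0)),
                         bc_dirichlet("y==max", c(0, 10))),
                    solve_config(steps = 10))
sol
#> <solve_result> converged = TRUE at t = 1.000, max |u| = 10.44 mm, J in [0.9852, 1.0823]

# the stiff inclusion resists volume change more than the matrix
round(tapply(abs(sol$J - 1), mesh$regions, mean), 4)
#>      0      1
#> 0.0248 0.0013
```

The interior of both phases keeps exact 1 mm squares; only the 44 cells
crossed by the circle are split into polygon pairs. At 100% nominal stretch
the per-element area ratios `J` stay within ~8% of one (the material is
nearly incompressible), and the mean volumetric deviation inside the stiff
inclusion is ~20x smaller than in the matrix. Results export to legacy VTK
(`write_mesh_vtk`) for visualization, and `run_benchmark()` wires up the
packaged benchmark problems end to end. A thin command-line front end over
the same functions is installed at `inst/cli/polylat2d.R`.

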