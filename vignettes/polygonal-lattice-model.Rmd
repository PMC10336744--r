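---
title: "Polygonal lattice mechanics from segmented images"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Polygonal lattice mechanics from segmented images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(polylat)
```

## The model

`polylat` simulates the finite plane-strain deformation of heterogeneous
soft materials — tissue cross-sections, bone, engineered composites — on
polygonal lattices built directly from segmented images. The constitutive
model is a nearly incompressible neo-Hookean solid. Writing the in-plane
deformation gradient as $F$, with $I_1 = F\!:\!F$ and $J = \det F$, the
energy density used throughout is

$$ W(F) \;=\; \frac{\mu}{2}\,(I_1 - 2)\;-\;\mu\,(J-1)\;+\;\frac{K}{2}\,(J-1)^2 , $$

with shear modulus $\mu$ and volumetric modulus $K$ (both kPa; lengths in
mm, forces in mN per unit out-of-plane thickness). $W$ and its first
derivative vanish at $F = I$, and $K/\mu \gg 1$ makes the material nearly
incompressible (for $\mu = 1$, $K = 100$ kPa the effective Poisson ratio is
$K/(2(K+\mu)) \approx 0.495$).

On each convex polygonal element the two invariants are discretized
differently:

* **The $I_1$ part becomes springs.** With Wachspress generalized
  barycentric coordinates $\varphi_a$ on the element, the discrete
  deformation gradient is $F = \sum_a x^a \otimes \nabla\varphi_a$, and
  $\int \frac{\mu}{2} (I_1 - 2)\,dA$ is a quadratic form in the nodal
  positions with matrix $\mu M$,
  $M_{ab} = \int \nabla\varphi_a \cdot \nabla\varphi_b \, dA$. Because the
  rows of $M$ sum to zero (the gradients of a partition of unity sum to
  zero), this quadratic form is *exactly* a sum of pairwise springs
  $\sum_{a<b} \tfrac{k_{ab}}{2} |x^a - x^b|^2$ with $k_{ab} = -\mu M_{ab}$.
  Springs connect every vertex pair of a polygon, may be negative, and
  reduce to the intuitive edge+diagonal spring set on squares
  ($k_{\text{edge}} = \mu/6$, $k_{\text{diag}} = \mu/3$).
* **The $J$ part becomes an area penalty.** In plane strain the volume
  ratio of an element is its area ratio $A/A_0$, so the volumetric energy is
  the element-wise function
  $U_J = -\mu\,(A - A_0) + \tfrac{K}{2}\,(A - A_0)^2 / A_0$. The element
  carries a single $J$ per polygon, which is what lets low-order elements
  avoid volumetric locking at large $K/\mu$.

The linear $-\mu (A - A_0)$ term deserves a comment, because it is the one
place where the energy split is not the naive quadratic penalty. The spring
set is derived from $\tfrac{\mu}{2}(I_1 - 2)$, which is *not* stress-free at
$F = I$: it carries an isotropic reference tension $\mu$ (the same reason
the continuum density needs its $-\mu(J-1)$ term). The linear area term
cancels that tension exactly, so a free element is in equilibrium in its
reference configuration — a property the test suite checks directly, and
which would fail for the pure quadratic penalty at any finite $K$. The
alternative is still available as
`volumetric_form = "pure_quadratic"`; at $K/\mu = 100$ the two differ by
about 1% in the fields, which is also why benchmark "bulk modulus" values
are mapped one-to-one onto $K$.

Two exact discrete properties tie the lattice to the continuum and are used
as oracles throughout the tests:

* **Affine exactness.** Wachspress coordinates reproduce linear fields, so
  for any affine deformation of a single element the lattice energy equals
  $A_0\,W(F)$ to round-off. This is the bridge between the spring picture
  and the hyperelastic density.
* **Frame indifference.** Springs see only distances and $U_J$ only areas,
  so the energy is invariant under rigid motions by construction.

## Wachspress coordinates and quadrature

The Wachspress weight of vertex $i$ at a point $q$ is built from signed
triangle areas: the fixed area $B_i = A(p_{i-1}, p_i, p_{i+1})$ times the
product of the edge-triangle areas $A(p_j, p_{j+1}, q)$ over all edges not
adjacent to $i$. Dividing out the common product gives the rational form
$\varphi_i \propto B_i / (A_{i-1} A_i)$, which the package evaluates in
log-magnitude form so it stays well scaled for any polygon size. Gradients
are analytic, by the product rule applied to the same weights; they are
verified against central finite differences at $10^{-6}$. Values at
vertices and on edges are served by their known limits (Kronecker delta,
edge-wise linearity) instead of evaluating the rational form at its
removable singularities.

$M$ is integrated with a centroid-fan rule: order 1 places one point per
fan triangle, order 2 the interior three-point rule (barycentric
permutations of $2/3, 1/6, 1/6$), which is exact for quadratics and keeps
every quadrature point strictly inside the polygon — the mid-edge variant
of the same degree would put points on the polygon boundary, where the
rational gradients are singular. Two properties hold for *any* rule whose
weights sum to the area, and are tested as such: the rows of $M$ sum to
zero, and $\sum_{ab} M_{ab}\, p_a \cdot p_b = 2 A_0$.

On parallelograms (all interior grid cells) Wachspress coordinates are
bilinear, gradients are linear, and the order-2 rule integrates $M$
exactly. On irregular polygons the gradients are rational and the fan rule
leaves a small consistency error, visible as a residual force on a free
element at rest, of order $10^{-3}$–$10^{-2}$ relative for the plain fan.
`polygon_quadrature(..., refine = r)` therefore subdivides each fan
triangle into $4^{r-1}$ congruent pieces; assembly defaults to `refine = 2`
as a cost/accuracy compromise, and `refine = 4` reaches the $10^{-4}$ level
on well-shaped polygons. Near-sliver cells (short edges) converge slowly at
any practical rule because the gradient poles sit just outside the short
edge; this is a known limitation, and one reason Lloyd-relaxed meshes (few
slivers) behave better than raw Voronoi diagrams. The order-1 rule is kept
for completeness but on squares it samples only the fan diagonals and
leaves hourglass modes nearly unpenalized; order 2 is the default
everywhere.

## Meshing

**From images.** A segmented label image (integer label per phase, physical
pixel size, y-up, lower-left origin) is turned into a conforming mesh in
three steps. (1) Sub-pixel interface loops are extracted per phase by
marching squares at the 0.5 iso-level of the phase indicator
(`grDevices::contourLines` on the zero-padded indicator) and simplified by
Douglas–Peucker with tolerance 0.25 pixel — enough to remove the staircase
without moving the boundary more than a quarter pixel. Marching squares
chamfers right-angle image corners by half a pixel; at the recommended 10
px/mm this is negligible against the lattice length. (2) A uniform
background grid of spacing $h$ (the lattice length) is overlaid; cells away
from every loop stay $h \times h$ squares. (3) Each cell crossed by a loop
is split along the straight chord between the two points where the loop
crosses the cell boundary, giving the four cut topologies
triangle+pentagon, triangle+quadrilateral, two quadrilaterals, and two
triangles. Crossings within $0.01\,h$ of a cell corner are merged onto the
corner, and near-coincident crossings on one edge are merged with the same
tolerance; chords that collapse onto a cell edge after snapping are treated
as no cut. Crossing points are computed once per *global* grid edge, so the
two cells flanking an edge share bit-identical nodes and the mesh is
conforming by construction. Cells crossed more than twice raise an
"ambiguous cut" error that names the cell and asks for a smaller $h$ —
curvature below the cell size is a meshing error controlled by refinement,
not something the chord model tries to repair. Each element takes the label
of the phase containing its centroid (tested against the linearized loops,
not raw pixels, for consistency with the chord geometry).

**For homogeneous benchmark domains.** Fully polygonal meshes come from a
Lloyd-relaxed centroidal Voronoi tessellation: seeds sampled uniformly
(single integer seed, recorded in the result provenance), then repeatedly
moved to the centroids of their bounded Voronoi cells. Cells are clipped
exactly against the convex domain boundary, so convexity and exact area
conservation hold by construction; the supported domains (rectangles, the
Cook trapezoid with corners (0,0), (48,44), (48,60), (0,44) mm — the
community-standard instance of that benchmark) are convex, which is why no
boundary-reflection trick is needed. Bisector clipping uses a
nearest-first sweep with the standard security-radius cutoff. Lloyd
iterations decay the maximum seed movement by two orders of magnitude over
~50 iterations, though not strictly monotonically — the monotone quantity
is the CVT energy, and the tests assert the strong overall decay rather
than stepwise monotonicity.

## The solver

Quasi-static equilibria minimize total potential energy (strain energy
minus dead-load work) under a load factor ramped linearly in `steps`
increments (default 20). Dirichlet conditions are imposed by elimination;
"fixed" boundaries clamp both components, and a gripped tension boundary
prescribes the pulled component and clamps the tangential one, matching
the rigid-grip convention of the finite-element baselines this model is
compared against (a component can be freed by passing `NA`). Tractions are
dead loads lumped trapezoidally onto reference boundary edges, so the total
applied force is exactly traction × edge length.

Each load step opens with a linear predictor: rather than jolting only the
constrained nodes by the boundary increment (which badly distorts the
boundary elements on fine meshes), the tangent system at the previous
converged state is solved for the interior response to that increment, and
Newton then corrects from there — typically in three to five iterations per
step. Newton acts on the free coordinates with the analytic gradient and
sparse tangent. The spring Hessian is constant and positive
semi-definite; the area term contributes a rank-one part plus the shoelace
curvature scaled by $dU_J/dA$, which makes the tangent indefinite away from
the equilibrium path (a pressure-like geometric term). The factorization is
a sparse Cholesky whose symbolic analysis is computed once per solve (the
tangent's sparsity pattern is fixed by the mesh) and whose numeric factor
is updated in place each iteration; when it reports indefiniteness the
solver escalates a diagonal shift (modified Newton), reaching the
Gershgorin diagonal-dominance bound within a few attempts, and falls back
to scaled steepest descent as a last resort. A
backtracking line search (factor 0.5) accepts a step only if the potential
decreases (Armijo) *and* every element area stays positive — inverted
states have infinite energy by convention. Convergence is declared when the
largest nodal residual norm falls below $10^{-8}\,\mu_{\max}\,\bar h$; a
step that fails is bisected up to 5 times, and on final failure the last
stable load factor is returned with `converged = FALSE` rather than an
error. At convergence the reactions on constrained nodes balance the
applied loads to $10^{-6}$ relative, which the tests assert.

## Synthetic benchmark fixtures

All benchmark inputs are generated in code, bit-reproducibly from their
parameters and seed:

* `uniaxial` — 20 × 10 mm rectangle, bottom fixed, top displaced 10 mm
  vertically ($\lambda = 2$), $\mu = 1$, $K = 100$ kPa.
* `cook` — the Cook trapezoid, left edge clamped, 1 kPa vertical shear
  traction on the 16 mm right edge (total load 16 mN/mm).
* `circle_inclusion` — one circular inclusion in the benchmark rectangle.
  The source geometry does not pin the circle down; the package's declared
  default is radius 2.5 mm at the center, fully parameterized.
* `bilayer` — sinusoidal two-phase interface. Declared defaults: amplitude
  2 mm, one full period across the 20 mm width, mean height 5 mm.
* `composite16` — 60 × 100 mm sample with 16 radius-4 mm circular
  inclusions. The published layout is a visually regular grid without
  printed coordinates; the default is a centered 4 × 4 grid (15 mm
  horizontal, 25 mm vertical pitch, half-pitch inset), fully
  parameterized so any layout can be supplied.
* `femur_blob` — a synthetic stand-in for a segmented organ cross-section:
  a star-convex blob whose radius is a seeded low-order Fourier
  perturbation, $r(\theta) = r_0 (1 + \sum_{k=2}^{5} a_k \cos(k\theta +
  \phi_k))$, $|a_k| \le 0.08$. It is simple by construction and its area
  has the closed form $\pi r_0^2 (1 + \tfrac{1}{2}\sum a_k^2)$, used to
  validate the raster and the extracted boundary. It emulates the smooth,
  blobby outline of a real segmentation; it does not emulate thin necks,
  internal cavities, or segmentation noise, so passing these tests says
  nothing about topologically complex anatomies.

Material sets follow the benchmark convention: matrix $\mu = 1$, $K = 100$;
soft inclusion one tenth ($0.1 / 10$); hard inclusion ten times
($10 / 1000$ kPa).

Images are rasterized at 10 px/mm by default so the sub-pixel contour error
is far below the lattice length. The generator emulates clean, noise-free
segmentations with smooth interfaces; it does not emulate partial-volume
pixels, label noise, or touching inclusions, so the meshing tests bound
geometric fidelity (areas to ~2%, conformity exactly) but say nothing about
robustness to segmentation artifacts.

## Verification strategy and problem sizes

The test suite is built on independent oracles: closed forms (bilinear
integrals on the square, barycentric gradients on triangles, the
homogeneous uniaxial lateral stretch
$\lambda_2 = \lambda_1 (\mu + K)/(\mu + K \lambda_1^2) = 202/401$ at
$\lambda_1 = 2$, $\mu = 1$, $K = 100$), finite differences for every
derivative, and algebraic identities (spring form = quadratic form, affine
exactness, partition of unity). The convergence study solves the clamped
uniaxial benchmark on Lloyd meshes of 100/400/1600 elements against a
4×-finer reference of the same scheme, interpolates the reference
displacement at the coarse nodes with the element shape functions, and fits
the L2-error slope against $h = \sqrt{\text{area}/n}$; the package asserts
at least first-order convergence ($\ge 0.9$), and on the default ladder the
fitted slope comes out above one, which is common when the coarse and
reference solutions share the same discretization and boundary layers.
These sizes keep the whole study in the minutes range on a
single core while leaving a factor-16 area ratio between the coarsest mesh
and the reference; they are the package's default study, not a limit of
the method. Near-incompressibility is checked two ways: interior area
ratios stay within 5% of one at $K/\mu = 100$ under $\lambda = 2$ tension,
and the error against the exact homogeneous solution does not degrade as
$K/\mu$ grows from 10 to 100 (no locking signature). The large-strain
composite runs (tension to 20 mm, shear to 18 mm) and the blob bending are
smoke tests with invariant checklists — conformity, positive areas,
reaction balance — because no field-level reference values exist for them.

## Known limitations

* Convex polygons only; the Wachspress construction degenerates on concave
  elements, and the mesher never produces them.
* The chord model replaces the interface inside a cut cell by a straight
  segment; sub-cell curvature and multi-loop cells are refinement errors by
  design, reported as "ambiguous cut" rather than repaired.
* Quadrature consistency on near-sliver polygons is limited (see above).
* Dead loads only; no follower tractions, contact, dynamics, or arc-length
  continuation past limit points.
* One material per element; intra-element property gradients are not
  represented.
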