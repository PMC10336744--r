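# Element-level lattice mechanics: neo-Hookean plane-strain energy split into
# a spring (I1) part with constants derived from shape-function gradients and
# an area (J) part, plus analytic forces and tangents.

#' Neo-Hookean plane-strain material
#'
#' @param mu_kPa Shear modulus mu > 0 (kPa).
#' @param K_kPa Volumetric modulus K > 0 (kPa); `K/mu >> 1` marks the material
#'   as nearly incompressible.
#' @return Object of class `polylat_material`.
#' @export
material <- function(mu_kPa, K_kPa) {
  if (!is.finite(mu_kPa) || mu_kPa <= 0) stop("shear modulus must be > 0")
  if (!is.finite(K_kPa) || K_kPa <= 0) stop("volumetric modulus must be > 0")
  structure(list(mu = as.numeric(mu_kPa), K = as.numeric(K_kPa)),
            class = "polylat_material")
}

#' @export
print.polylat_material <- function(x, ...) {
  tag <- if (x$K / x$mu >= 50) " (nearly incompressible)" else ""
  cat(sprintf("<material> mu = %g kPa, K = %g kPa%s\n", x$mu, x$K, tag))
  invisible(x)
}

#' Continuum neo-Hookean plane-strain energy density
#'
#' `W(F) = mu/2 (I1 - 2) - mu (J - 1) + K/2 (J - 1)^2` with `I1 = F:F` and
#' `J = det F` of the in-plane deformation gradient. The reference state
#' `F = I` has zero energy and zero first Piola stress; the `-mu (J - 1)`
#' term cancels the reference stress of the I1 part.
#'
#' @param F 2 x 2 deformation gradient, `det F > 0`.
#' @param mat A [material()].
#' @return List with `W` (kPa), `I1`, `J`.
#' @export
continuum_density <- function(F, mat) {
  J <- F[1L, 1L] * F[2L, 2L] - F[1L, 2L] * F[2L, 1L]
  if (J <= 0) stop("inadmissible state: det F <= 0")
  I1 <- sum(F * F)
  W <- 0.5 * mat$mu * (I1 - 2) - mat$mu * (J - 1) + 0.5 * mat$K * (J - 1)^2
  list(W = W, I1 = I1, J = J)
}

#' Lattice springs of a polygonal element
#'
#' Derives the spring constants `k_ab = -mu M_ab` (a < b) from the
#' shape-function gradient matrix M. By the zero row sums of M, the spring
#' energy `sum_{a<b} k_ab/2 |x_a - x_b|^2` equals the quadratic form
#' `mu/2 sum_ab M_ab x_a . x_b` for every nodal configuration. Springs may be
#' negative; for each node a, `sum_{b != a} k_ab = mu M_aa`.
#'
#' @param poly A [convex_polygon()].
#' @param mu Shear modulus (kPa).
#' @param rule Quadrature rule; default order 2.
#' @return data.frame with columns `a`, `b` (node-in-element indices, a < b)
#'   and `k` (kPa per unit thickness).
#' @export
springs_from_polygon <- function(poly, mu, rule = polygon_quadrature(poly, 2L)) {
  M <- grad_stiffness_matrix(poly, rule)
  idx <- which(upper.tri(M), arr.ind = TRUE)
  data.frame(a = idx[, 1L], b = idx[, 2L], k = -mu * M[idx])
}

#' Element operator of a polygonal lattice element
#'
#' Precomputes everything element-level energies need: the reference area A0,
#' the gradient-product matrix M (and the spring set derived from it), and the
#' reference vertex coordinates.
#'
#' @param poly A [convex_polygon()] in the reference configuration.
#' @param node_indices Global node indices of the vertices (same order).
#' @param mu Shear modulus of the element's material (kPa).
#' @param region Material region label.
#' @param rule_order Quadrature order for M (default 2).
#' @param quad_refine Fan subdivision level of the rule (default 2), see
#'   [polygon_quadrature()].
#' @return Object of class `element_operator`.
#' @export
element_operator <- function(poly, node_indices, mu, region = "domain",
                             rule_order = 2L, quad_refine = 2L) {
  M <- grad_stiffness_matrix(poly,
                             polygon_quadrature(poly, rule_order, quad_refine))
  structure(list(node_indices = as.integer(node_indices),
                 n = poly$n, A0 = poly$area, mu = mu, M = M,
                 X = poly$vertices, region = region),
            class = "element_operator")
}

#' Springs of an element operator
#' @param op An [element_operator()].
#' @return data.frame as in [springs_from_polygon()].
#' @export
element_springs <- function(op) {
  idx <- which(upper.tri(op$M), arr.ind = TRUE)
  data.frame(a = idx[, 1L], b = idx[, 2L], k = -op$mu * op$M[idx])
}

#' Deformed area of an element
#'
#' Shoelace area of the deformed vertex loop; equals A0 in the reference
#' configuration, negative for an inverted element.
#'
#' @param x n x 2 matrix of deformed vertex coordinates (CCW order).
#' @return Signed area (mm^2).
#' @export
element_area <- function(x) polygon_area(x)

#' Stretching (I1) energy of an element
#'
#' `U_I1 = sum_{a<b} k_ab/2 |x_a - x_b|^2 - mu A0`, offset so the reference
#' configuration has zero energy. Invariant under rigid motions (springs see
#' only distances) and exactly equal to `mu/2 (I1 - 2) A0` for any affine
#' configuration, by linear reproduction of the shape functions.
#'
#' @param op An [element_operator()].
#' @param x n x 2 matrix of deformed vertex coordinates.
#' @return Energy (kPa mm^2 per unit thickness).
#' @export
element_energy_I1 <- function(op, x) {
  0.5 * op$mu * sum(x * (op$M %*% x)) - op$mu * op$A0
}

#' Volumetric (area) energy of an element
#'
#' Default compensated form `U_J = -mu (A - A0) + K/2 (A - A0)^2 / A0`: zero
#' at the reference area, with slope `-mu` there so that a free element is in
#' equilibrium at rest (the I1 springs carry a reference tension `+mu` that
#' this term cancels). The `pure_quadratic` form drops the linear term.
#'
#' @param op An [element_operator()].
#' @param x n x 2 matrix of deformed vertex coordinates.
#' @param mat A [material()].
#' @param form `"compensated"` (default) or `"pure_quadratic"`.
#' @return Energy (kPa mm^2 per unit thickness).
#' @export
element_energy_J <- function(op, x, mat,
                             form = c("compensated", "pure_quadratic")) {
  form <- match.arg(form)
  A <- polygon_area(x)
  if (A <= 0) stop("inadmissible state: inverted element (A <= 0)")
  dA <- A - op$A0
  U <- 0.5 * mat$K * dA^2 / op$A0
  if (form == "compensated") U <- U - mat$mu * dA
  U
}

# Gradient of the shoelace area with respect to the vertex coordinates:
# dA/dx_a = perp(x_{a+1} - x_{a-1}) / 2.
#' @noRd
area_gradient <- function(x) {
  n <- nrow(x)
  ip1 <- c(seq_len(n)[-1L], 1L)
  im1 <- c(n, seq_len(n - 1L))
  cbind(0.5 * (x[ip1, 2L] - x[im1, 2L]), 0.5 * (x[im1, 1L] - x[ip1, 1L]))
}

#' Nodal forces of an element
#'
#' Gradient of `element_energy_I1 + element_energy_J` with respect to the
#' deformed vertex coordinates.
#'
#' @inheritParams element_energy_J
#' @return n x 2 matrix of forces (kPa mm per unit thickness).
#' @export
element_forces <- function(op, x, mat,
                           form = c("compensated", "pure_quadratic")) {
  form <- match.arg(form)
  A <- polygon_area(x)
  if (A <= 0) stop("inadmissible state: inverted element (A <= 0)")
  dUdA <- mat$K * (A - op$A0) / op$A0
  if (form == "compensated") dUdA <- dUdA - mat$mu
  op$mu * (op$M %*% x) + dUdA * area_gradient(x)
}

#' Tangent stiffness of an element
#'
#' Symmetric `2n x 2n` matrix in stacked ordering (all x-dofs then all
#' y-dofs). The I1 contribution `mu M` is constant (the spring energy is
#' quadratic); the area term contributes a rank-one part
#' `K/A0 gA gA^T` plus the constant shoelace curvature scaled by `dU_J/dA`.
#'
#' @inheritParams element_energy_J
#' @return `2n x 2n` symmetric matrix.
#' @export
element_tangent <- function(op, x, mat,
                            form = c("compensated", "pure_quadratic")) {
  form <- match.arg(form)
  n <- op$n
  A <- polygon_area(x)
  if (A <= 0) stop("inadmissible state: inverted element (A <= 0)")
  dUdA <- mat$K * (A - op$A0) / op$A0
  if (form == "compensated") dUdA <- dUdA - mat$mu
  d2 <- mat$K / op$A0
  g <- area_gradient(x)
  gv <- c(g[, 1L], g[, 2L])
  K <- d2 * tcrossprod(gv)
  K[seq_len(n), seq_len(n)] <- K[seq_len(n), seq_len(n)] + op$mu * op$M
  K[n + seq_len(n), n + seq_len(n)] <- K[n + seq_len(n), n + seq_len(n)] + op$mu * op$M
  # shoelace curvature: d2A/dx_a dy_{a+1} = +1/2, d2A/dx_a dy_{a-1} = -1/2
  ip1 <- c(seq_len(n)[-1L], 1L)
  im1 <- c(n, seq_len(n - 1L))
  H <- matrix(0, n, n)
  H[cbind(seq_len(n), ip1)] <- H[cbind(seq_len(n), ip1)] + 0.5
  H[cbind(seq_len(n), im1)] <- H[cbind(seq_len(n), im1)] - 0.5
  K[seq_len(n), n + seq_len(n)] <- K[seq_len(n), n + seq_len(n)] + dUdA * H
  K[n + seq_len(n), seq_len(n)] <- K[n + seq_len(n), seq_len(n)] + dUdA * t(H)
  K
}

#' Element deformation gradient at a reference point
#'
#' `F = sum_a x_a grad(phi_a)^T` evaluated at a point of the reference
#' polygon (default its centroid).
#'
#' @param op An [element_operator()].
#' @param x n x 2 matrix of deformed vertex coordinates.
#' @param at Length-2 reference point; default the reference centroid.
#' @return 2 x 2 deformation gradient.
#' @export
element_deformation_gradient <- function(op, x, at = NULL) {
  poly <- convex_polygon(op$X)
  if (is.null(at)) at <- polygon_centroid(op$X)
  G <- wachspress_gradients(poly, at)
  crossprod(x, G)
}
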