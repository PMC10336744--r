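# Element mechanics: springs from shape-function gradients, the I1/J energy
# split, forces, tangents, and the continuum bridge.

test_that("unit-square springs are 1/6 on edges and 1/3 on diagonals", {
  sp <- springs_from_polygon(unit_square(), mu = 1)
  k <- function(a, b) sp$k[sp$a == a & sp$b == b]
  expect_equal(c(k(1, 2), k(2, 3), k(3, 4), k(1, 4)), rep(1 / 6, 4))
  expect_equal(c(k(1, 3), k(2, 4)), rep(1 / 3, 2))
  # node sum rule: sum_b k_ab = mu * M_aa
  M <- grad_stiffness_matrix(unit_square())
  for (a in 1:4) {
    expect_equal(sum(sp$k[sp$a == a | sp$b == a]), M[a, a])
  }
})

test_that("equilateral triangle springs are equal by symmetry", {
  th <- 2 * pi * (0:2) / 3
  tri <- convex_polygon(cbind(cos(th), sin(th)))
  sp <- springs_from_polygon(tri, mu = 1)
  expect_equal(sp$k, rep(sp$k[1], 3))
})

test_that("spring-form energy equals the quadratic form for any configuration", {
  set.seed(4)
  poly <- rand_convex_polygon(5)
  mu <- 1.7
  rule <- polygon_quadrature(poly, 2L)
  M <- grad_stiffness_matrix(poly, rule)
  sp <- springs_from_polygon(poly, mu, rule)
  for (rep in 1:10) {
    x <- poly$vertices + matrix(rnorm(10, sd = 0.3), 5L, 2L)
    quad <- 0.5 * mu * sum(x * (M %*% x))
    springs <- sum(0.5 * sp$k *
                     rowSums((x[sp$a, , drop = FALSE] - x[sp$b, , drop = FALSE])^2))
    expect_equal(springs, quad, tolerance = 1e-12)
  }
})

test_that("reference spring energy equals mu * A0", {
  set.seed(9)
  for (n in c(4, 6, 8)) {
    poly <- rand_convex_polygon(n)
    op <- element_operator(poly, seq_len(n), mu = 2.5)
    sp <- element_springs(op)
    eref <- sum(0.5 * sp$k *
                  rowSums((poly$vertices[sp$a, , drop = FALSE] -
                             poly$vertices[sp$b, , drop = FALSE])^2))
    expect_equal(eref, 2.5 * poly$area, tolerance = 1e-10 * poly$area)
  }
})

test_that("I1 energy vanishes for rigid motions and matches the continuum for affine maps", {
  op <- element_operator(unit_square(), 1:4, mu = 1)
  X <- unit_square()$vertices
  expect_equal(element_energy_I1(op, X), 0)
  R <- rand_rotation(37 * pi / 180)
  expect_equal(element_energy_I1(op, X %*% t(R) + 2), 0, tolerance = 1e-12)
  # F = diag(2, 1/2): U_I1 = mu/2 (I1 - 2) A0 = 1.125
  expect_equal(element_energy_I1(op, X %*% diag(c(2, 0.5))), 1.125)
})

test_that("deformed element areas follow the shoelace formula", {
  X <- unit_square()$vertices
  expect_equal(element_area(X), 1)
  expect_equal(element_area(2 * X), 4)
  set.seed(2)
  poly <- rand_convex_polygon(6)
  shear <- matrix(c(1, 0, 0.7, 1), 2L, 2L)  # det = 1
  expect_equal(element_area(poly$vertices %*% t(shear)), poly$area,
               tolerance = 1e-12)
})

test_that("volumetric energy is zero at the reference and matches the stated form", {
  op <- element_operator(unit_square(), 1:4, mu = 1)
  mat <- material(1, 100)
  X <- unit_square()$vertices
  expect_equal(element_energy_J(op, X, mat), 0)
  # isotropic scale by sqrt(2): A = 2, U_J = -1 * 1 + 50 * 1 = 49
  expect_equal(element_energy_J(op, sqrt(2) * X, mat), 49)
  shear <- matrix(c(1, 0, 0.4, 1), 2L, 2L)
  expect_equal(element_energy_J(op, X %*% t(shear), mat), 0, tolerance = 1e-12)
  expect_error(element_energy_J(op, X[4:1, ], mat), "inverted")
  # pure_quadratic drops the compensation term
  expect_equal(element_energy_J(op, sqrt(2) * X, mat, form = "pure_quadratic"), 50)
})

test_that("continuum density reproduces the neo-Hookean values and stationarity", {
  mat <- material(1, 100)
  ref <- continuum_density(diag(2), mat)
  expect_equal(c(ref$W, ref$I1, ref$J), c(0, 2, 1))
  d <- continuum_density(diag(c(2, 0.5)), mat)
  expect_equal(c(d$W, d$I1, d$J), c(1.125, 4.25, 1))
  expect_error(continuum_density(diag(c(1, -1)), mat), "inadmissible")
  # lateral stretch that makes W stationary at lam1 = 2: solve dW/dlam2 = 0
  # numerically and compare with the closed form lam1 (mu + K) / (mu + K lam1^2)
  dW <- function(l2) {
    eps <- 1e-6
    (continuum_density(diag(c(2, l2 + eps)), mat)$W -
       continuum_density(diag(c(2, l2 - eps)), mat)$W) / (2 * eps)
  }
  root <- stats::uniroot(dW, c(0.2, 1))$root
  expect_equal(root, 202 / 401, tolerance = 1e-5)
})

test_that("element forces and tangent match finite differences of the energy", {
  set.seed(17)
  mat <- material(1.3, 40)
  for (n in c(4, 6)) {
    poly <- rand_convex_polygon(n)
    op <- element_operator(poly, seq_len(n), mu = mat$mu)
    x <- poly$vertices %*% t(rand_affine()) +
      matrix(rnorm(2 * n, sd = 0.05), n, 2L)
    etot <- function(xx) element_energy_I1(op, xx) + element_energy_J(op, xx, mat)
    f <- element_forces(op, x, mat)
    expect_equal(unclass(f), fd_gradient(etot, x), tolerance = 1e-6,
                 ignore_attr = TRUE)
    K <- element_tangent(op, x, mat)
    expect_equal(K, t(K))
    # forces are unchanged by rigid translation
    expect_equal(element_forces(op, x + 5, mat), f, tolerance = 1e-9,
                 ignore_attr = TRUE)
  }
})

test_that("a free element is in equilibrium at rest", {
  # exact for grid squares
  op <- element_operator(unit_square(), 1:4, mu = 1)
  f <- element_forces(op, unit_square()$vertices, material(1, 100))
  expect_lt(max(abs(f)), 1e-8 * 4)
  # within quadrature accuracy for irregular polygons (refined fan rule)
  set.seed(29)
  for (n in c(4, 5, 6, 7)) {
    poly <- rand_convex_polygon(n, min_gap = 0.5)
    per <- sum(sqrt(rowSums((poly$vertices[c(2:n, 1), ] - poly$vertices)^2)))
    op <- element_operator(poly, seq_len(n), mu = 1, quad_refine = 4L)
    f <- element_forces(op, poly$vertices, material(1, 100))
    expect_lt(max(abs(f)) / per, 1e-4)
  }
})

test_that("lattice element energy is affine-exact against the continuum density", {
  set.seed(31)
  mat <- material(2, 150)
  for (rep in 1:8) {
    n <- sample(3:8, 1)
    poly <- rand_convex_polygon(n, shift = rnorm(2))
    op <- element_operator(poly, seq_len(n), mu = mat$mu)
    F <- rand_affine()
    x <- poly$vertices %*% t(F)
    e <- element_energy_I1(op, x) + element_energy_J(op, x, mat)
    expect_equal(e, poly$area * continuum_density(F, mat)$W,
                 tolerance = 1e-10)
  }
})

test_that("element energy is frame-indifferent", {
  set.seed(37)
  mat <- material(1, 100)
  poly <- rand_convex_polygon(6)
  op <- element_operator(poly, 1:6, mu = 1)
  x <- poly$vertices %*% t(rand_affine())
  e0 <- element_energy_I1(op, x) + element_energy_J(op, x, mat)
  for (rep in 1:5) {
    xr <- sweep(x %*% t(rand_rotation()), 2, rnorm(2), "+")
    er <- element_energy_I1(op, xr) + element_energy_J(op, xr, mat)
    expect_equal(er, e0, tolerance = 1e-12)
  }
})
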