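# Wachspress coordinates, their gradients, polygon quadrature and the
# gradient-product matrix M.

test_that("signed triangle area has the right sign, value and degeneracy", {
  expect_equal(signed_triangle_area(c(0, 0), c(1, 0), c(0, 1)), 0.5)
  expect_equal(signed_triangle_area(c(0, 0), c(1, 1), c(2, 2)), 0)
  expect_equal(signed_triangle_area(c(0, 0), c(0, 1), c(1, 0)), -0.5)
  # antisymmetric under swapping two arguments
  set.seed(1)
  for (i in 1:5) {
    p <- matrix(rnorm(6), 3L, 2L)
    expect_equal(signed_triangle_area(p[1, ], p[2, ], p[3, ]),
                 -signed_triangle_area(p[2, ], p[1, ], p[3, ]))
  }
})

test_that("Wachspress values are symmetric where the polygon is", {
  expect_equal(wachspress_values(unit_square(), c(0.5, 0.5)), rep(0.25, 4))
  th <- 2 * pi * (0:4) / 5 + pi / 2
  pent <- convex_polygon(cbind(cos(th), sin(th)))
  expect_equal(wachspress_values(pent, c(0, 0)), rep(0.2, 5), tolerance = 1e-12)
})

test_that("partition of unity, positivity and linear reproduction hold on random polygons", {
  set.seed(42)
  for (n in 3:8) {
    for (rep in 1:5) {
      poly <- rand_convex_polygon(n, shift = rnorm(2))
      q <- rand_point_in(poly)
      w <- wachspress_values(poly, q)
      expect_equal(sum(w), 1, tolerance = 1e-12)
      expect_true(all(w >= 0))
      expect_lt(max(abs(colSums(w * poly$vertices) - q)), 1e-12)
    }
  }
})

test_that("values on the closure give the vertex delta and edge linearity", {
  set.seed(5)
  poly <- rand_convex_polygon(6)
  # Kronecker delta at vertices
  for (i in 1:6) {
    w <- wachspress_values(poly, poly$vertices[i, ])
    expect_equal(w, as.numeric(seq_len(6) == i), tolerance = 1e-12)
  }
  # linear along an edge
  t <- 0.3
  q <- (1 - t) * poly$vertices[2, ] + t * poly$vertices[3, ]
  w <- wachspress_values(poly, q)
  expect_equal(w[2], 1 - t, tolerance = 1e-9)
  expect_equal(w[3], t, tolerance = 1e-9)
  expect_equal(sum(w[-(2:3)]), 0)
})

test_that("values error for exterior points", {
  poly <- unit_square()
  expect_error(wachspress_values(poly, c(2, 0.5)), "outside")
})

test_that("gradients match the bilinear and barycentric closed forms", {
  # on a square Wachspress coordinates are bilinear: d/dx[(1-x)(1-y)] at the
  # center is (-0.5, -0.5)
  G <- wachspress_gradients(unit_square(), c(0.5, 0.5))
  expect_equal(G[1, ], c(-0.5, -0.5))
  # on a triangle they are the barycentric coordinates: constant gradients
  tri <- convex_polygon(rbind(c(0, 0), c(2, 0), c(0, 1)))
  Tm <- rbind(c(2, 0), c(0, 1))  # edge matrix
  Ginv <- solve(t(Tm))
  set.seed(8)
  for (rep in 1:3) {
    q <- rand_point_in(tri)
    G <- wachspress_gradients(tri, q)
    expect_equal(G[2, ], Ginv[, 1], tolerance = 1e-12)
    expect_equal(G[3, ], Ginv[, 2], tolerance = 1e-12)
    expect_equal(G[1, ], -Ginv[, 1] - Ginv[, 2], tolerance = 1e-12)
  }
})

test_that("analytic gradients match central finite differences", {
  set.seed(13)
  for (n in 3:8) {
    poly <- rand_convex_polygon(n)
    q <- rand_point_in(poly)
    G <- wachspress_gradients(poly, q)
    eps <- 1e-7
    Gfd <- cbind((wachspress_values(poly, q + c(eps, 0)) -
                    wachspress_values(poly, q - c(eps, 0))) / (2 * eps),
                 (wachspress_values(poly, q + c(0, eps)) -
                    wachspress_values(poly, q - c(0, eps))) / (2 * eps))
    expect_lt(max(abs(G - Gfd)), 1e-6)
    # gradients sum to zero; linear reproduction differentiates to identity
    expect_lt(max(abs(colSums(G))), 1e-12)
    expect_equal(crossprod(poly$vertices, G), diag(2), tolerance = 1e-11,
                 ignore_attr = TRUE)
  }
})

test_that("polygon quadrature conserves area and integrates quadratics on the square", {
  r1 <- polygon_quadrature(unit_square(), 1L)
  expect_equal(nrow(r1$points), 4L)
  expect_equal(r1$weights, rep(0.25, 4))
  r2 <- polygon_quadrature(unit_square(), 2L)
  expect_equal(sum(r2$weights), 1)
  expect_equal(sum(r2$weights * r2$points[, 1]), 0.5)
  expect_equal(sum(r2$weights * r2$points[, 1]^2), 1 / 3)
  set.seed(21)
  for (n in c(3, 5, 8)) {
    poly <- rand_convex_polygon(n)
    for (refine in 1:3) {
      r <- polygon_quadrature(poly, 2L, refine)
      expect_equal(sum(r$weights), poly$area, tolerance = 1e-13)
      expect_true(all(point_in_polygon(r$points, poly)))
    }
  }
})

test_that("M on the unit square matches the exact bilinear integrals", {
  M <- grad_stiffness_matrix(unit_square())
  expect_equal(diag(M), rep(2 / 3, 4))
  expect_equal(M[1, 2], -1 / 6)
  expect_equal(M[1, 3], -1 / 3)
  expect_equal(M, t(M))
})

test_that("M row sums vanish and the reference identity holds for any area-exact rule", {
  set.seed(33)
  for (n in 3:8) {
    poly <- rand_convex_polygon(n, shift = rnorm(2))
    for (spec in list(c(1L, 1L), c(2L, 1L), c(2L, 2L))) {
      M <- grad_stiffness_matrix(poly, polygon_quadrature(poly, spec[1], spec[2]))
      expect_lt(max(abs(rowSums(M))), 1e-12)
      expect_equal(sum(M * tcrossprod(poly$vertices)), 2 * poly$area,
                   tolerance = 1e-12)
    }
  }
})
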