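# Wachspress generalized barycentric coordinates on convex polygons, their
# analytic gradients, centroid-fan quadrature, and the shape-function gradient
# product matrix that the lattice springs are derived from.
#
# For a CCW convex polygon with vertices p_1..p_n the Wachspress weight of
# vertex i at a query point q is
#     w_i(q) = A(p_{i-1}, p_i, p_{i+1}) * prod_{j != i-1, i} A(p_j, p_{j+1}, q)
# and phi_i = w_i / sum_j w_j. Dividing out the common positive factor
# prod_j A_j gives the rational form phi_i ~ B_i / (A_{i-1} A_i), which is
# evaluated here in log-magnitude form so the products stay well scaled for
# any n.

# Edge triangle areas A_j = A(p_j, p_{j+1}, q), vectorized over j.
#' @noRd
edge_areas <- function(v, q) {
  x <- v[, 1L]; y <- v[, 2L]
  xn <- c(x[-1L], x[1L]); yn <- c(y[-1L], y[1L])
  0.5 * ((xn - x) * (q[2L] - y) - (yn - y) * (q[1L] - x))
}

#' Wachspress shape-function values
#'
#' Evaluates the Wachspress generalized barycentric coordinates of a convex
#' polygon at a query point. The values form a partition of unity, are
#' non-negative inside the polygon, reduce to the Kronecker delta at vertices,
#' are linear along each edge, and reproduce linear fields exactly:
#' `sum_i phi_i(q) p_i = q`.
#'
#' Points on the closure (edges or vertices) are served by the known limits
#' (edge-wise linear interpolation, vertex delta) rather than by evaluating
#' the rational form at its removable singularities.
#'
#' @param poly A [convex_polygon()].
#' @param q Length-2 query point inside the polygon or on its boundary.
#' @return Numeric vector of n shape-function values.
#' @export
wachspress_values <- function(poly, q) {
  v <- poly$vertices; n <- poly$n
  A <- edge_areas(v, q)
  ex <- c(v[-1L, 1L], v[1L, 1L]) - v[, 1L]
  ey <- c(v[-1L, 2L], v[1L, 2L]) - v[, 2L]
  len <- sqrt(ex^2 + ey^2)
  hgt <- 2 * A / len                       # distance of q from each edge line
  edge_tol <- 1e-9 * poly$scale
  if (any(hgt < -edge_tol)) {
    stop("query point lies outside the polygon (or the polygon is degenerate)")
  }
  on_edge <- which(hgt <= edge_tol)
  if (length(on_edge)) {
    phi <- numeric(n)
    if (length(on_edge) == 1L) {
      j <- on_edge
      t <- ((q[1L] - v[j, 1L]) * ex[j] + (q[2L] - v[j, 2L]) * ey[j]) / len[j]^2
      t <- min(max(t, 0), 1)
      phi[j] <- 1 - t
      phi[if (j == n) 1L else j + 1L] <- t
    } else if (length(on_edge) == 2L) {
      j1 <- on_edge[1L]; j2 <- on_edge[2L]
      # adjacent edges meet at a vertex
      if (j2 == j1 + 1L) {
        phi[j2] <- 1
      } else if (j1 == 1L && j2 == n) {
        phi[1L] <- 1
      } else {
        stop("query point lies on two non-adjacent edges; degenerate polygon")
      }
    } else {
      stop("query point lies on more than two edges; degenerate polygon")
    }
    return(phi)
  }
  im1 <- c(n, seq_len(n - 1L))
  ip1 <- c(seq_len(n)[-1L], 1L)
  B <- 0.5 * ((v[, 1L] - v[im1, 1L]) * (v[ip1, 2L] - v[im1, 2L]) -
                (v[, 2L] - v[im1, 2L]) * (v[ip1, 1L] - v[im1, 1L]))
  # a vertex collinear with its neighbors has zero fixed triangle area and
  # hence zero weight everywhere in the interior (the limit of the rational
  # form); only genuinely negative areas mean a non-convex polygon
  B_tol <- 1e-10 * poly$scale^2
  if (any(B < -B_tol)) {
    stop("degenerate (non-convex) polygon in Wachspress weights")
  }
  pos <- B > B_tol
  if (!any(pos)) stop("degenerate polygon: all vertices collinear")
  w <- numeric(n)
  logw <- log(B[pos]) - log(A[im1][pos]) - log(A[pos])
  w[pos] <- exp(logw - max(logw))
  w / sum(w)
}

#' Wachspress shape-function gradients
#'
#' Analytic gradients obtained by the product rule applied to the Wachspress
#' weights: with `g_i = grad(w_i)/w_i = sum_{j != i-1, i} R_j / A_j`, where
#' `R_j = perp(p_{j+1} - p_j)/2` is the gradient of the edge triangle area
#' `A_j` with respect to the query point, the normalized gradients are
#' `grad(phi_i) = phi_i (g_i - sum_j phi_j g_j)`. They satisfy
#' `sum_i grad(phi_i) = 0` and `sum_i p_i grad(phi_i)^T = I` (the gradient of
#' the linear-reproduction identity).
#'
#' @param poly A [convex_polygon()].
#' @param q Length-2 query point strictly inside the polygon.
#' @return n x 2 matrix of gradients (1/mm).
#' @export
wachspress_gradients <- function(poly, q) {
  v <- poly$vertices; n <- poly$n
  A <- edge_areas(v, q)
  ex <- c(v[-1L, 1L], v[1L, 1L]) - v[, 1L]
  ey <- c(v[-1L, 2L], v[1L, 2L]) - v[, 2L]
  len <- sqrt(ex^2 + ey^2)
  edge_tol <- 1e-9 * poly$scale
  if (any(2 * A / len <= edge_tol)) {
    stop("Wachspress gradients require a strictly interior query point")
  }
  phi <- wachspress_values(poly, q)
  # R_j / A_j with R_j = 0.5 * perp(edge_j)
  rx <- -0.5 * ey / A
  ry <- 0.5 * ex / A
  Sx <- sum(rx); Sy <- sum(ry)
  im1 <- c(n, seq_len(n - 1L))
  gx <- Sx - rx[im1] - rx
  gy <- Sy - ry[im1] - ry
  gbx <- sum(phi * gx); gby <- sum(phi * gy)
  cbind(phi * (gx - gbx), phi * (gy - gby))
}

#' Quadrature rule on a convex polygon
#'
#' Fan-triangulates the polygon from its centroid and places a degree-1 or
#' degree-2 rule on each fan triangle. Order 1 uses one centroid point per
#' triangle; order 2 uses the interior three-point rule (barycentric
#' permutations of 2/3, 1/6, 1/6), exact for quadratics on each triangle.
#' All points are strictly inside the polygon and the weights sum to the
#' polygon area to machine precision. Degenerate (zero-area) fan triangles
#' contribute nothing.
#'
#' Because the shape-function gradients are rational (not polynomial) on
#' general polygons, `refine > 1` subdivides every fan triangle into
#' `4^(refine-1)` congruent sub-triangles before placing the rule, which
#' sharpens the integrals entering [grad_stiffness_matrix()] without
#' changing any of the rule's invariants (on parallelograms, where the
#' shape functions are bilinear, the result is unchanged).
#'
#' @param poly A [convex_polygon()].
#' @param order Integer 1 or 2 (default 2).
#' @param refine Fan subdivision level, >= 1 (default 1: the plain fan).
#' @return Object of class `quadrature_rule` with `points` (k x 2 matrix, mm)
#'   and `weights` (length k, mm^2).
#' @export
polygon_quadrature <- function(poly, order = 2L, refine = 1L) {
  if (!order %in% c(1L, 2L)) stop("quadrature order must be 1 or 2")
  if (refine < 1L) stop("refine must be >= 1")
  v <- poly$vertices; n <- poly$n
  cen <- polygon_centroid(v)
  subdiv <- function(tri, lev) {
    if (lev == 0L) return(list(tri))
    m12 <- (tri[1L, ] + tri[2L, ]) / 2
    m23 <- (tri[2L, ] + tri[3L, ]) / 2
    m13 <- (tri[1L, ] + tri[3L, ]) / 2
    c(subdiv(rbind(tri[1L, ], m12, m13), lev - 1L),
      subdiv(rbind(m12, tri[2L, ], m23), lev - 1L),
      subdiv(rbind(m13, m23, tri[3L, ]), lev - 1L),
      subdiv(rbind(m12, m23, m13), lev - 1L))
  }
  pts <- list(); wts <- list()
  for (i in seq_len(n)) {
    a <- v[i, ]; b <- v[if (i == n) 1L else i + 1L, ]
    if (abs(signed_triangle_area(cen, a, b)) <= 1e-14 * poly$scale^2) next
    for (tri in subdiv(rbind(cen, a, b), refine - 1L)) {
      at <- signed_triangle_area(tri[1L, ], tri[2L, ], tri[3L, ])
      if (order == 1L) {
        pts[[length(pts) + 1L]] <- matrix(colMeans(tri), 1L, 2L)
        wts[[length(wts) + 1L]] <- at
      } else {
        pts[[length(pts) + 1L]] <-
          rbind((4 * tri[1L, ] + tri[2L, ] + tri[3L, ]) / 6,
                (tri[1L, ] + 4 * tri[2L, ] + tri[3L, ]) / 6,
                (tri[1L, ] + tri[2L, ] + 4 * tri[3L, ]) / 6)
        wts[[length(wts) + 1L]] <- rep(at / 3, 3L)
      }
    }
  }
  structure(list(points = do.call(rbind, pts), weights = unlist(wts)),
            class = "quadrature_rule")
}

#' Shape-function gradient product matrix
#'
#' Computes the n x n symmetric matrix
#' `M_ab = integral over the polygon of grad(phi_a) . grad(phi_b) dA`
#' using the supplied quadrature rule. Because the gradients sum to zero at
#' every point, every row of M sums to zero; and because linear fields are
#' reproduced exactly, `sum_ab M_ab (p_a . p_b) = 2 * area` for any rule whose
#' weights sum to the area. The lattice spring constants are
#' `k_ab = -mu * M_ab`.
#'
#' @param poly A [convex_polygon()].
#' @param rule A [polygon_quadrature()] rule on the same polygon; default the
#'   order-2 rule.
#' @return n x n symmetric numeric matrix (dimensionless).
#' @export
grad_stiffness_matrix <- function(poly, rule = polygon_quadrature(poly, 2L)) {
  n <- poly$n
  M <- matrix(0, n, n)
  for (k in seq_along(rule$weights)) {
    G <- wachspress_gradients(poly, rule$points[k, ])
    M <- M + rule$weights[k] * tcrossprod(G)
  }
  (M + t(M)) / 2
}
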