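# Shared fixtures: random convex polygons (vertices on an ellipse with a
# minimum angular gap, so shapes are irregular but not slivers), interior
# sample points, and small finite-difference helpers.

unit_square <- function() {
  convex_polygon(rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1)))
}

rand_convex_polygon <- function(n, rx = 1.4, ry = 1, min_gap = 1.5 / n,
                                shift = c(0, 0)) {
  repeat {
    a <- sort(stats::runif(n, 0, 2 * pi))
    if (min(diff(c(a, a[1L] + 2 * pi))) > min_gap) break
  }
  convex_polygon(cbind(rx * cos(a) + shift[1L], ry * sin(a) + shift[2L]))
}

rand_point_in <- function(poly) {
  w <- stats::runif(poly$n) + 0.1
  w <- w / sum(w)
  colSums(w * poly$vertices)
}

rand_rotation <- function(theta = stats::runif(1, 0, 2 * pi)) {
  matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2L, 2L)
}

# a random affine map with positive determinant, bounded away from inversion
rand_affine <- function() {
  repeat {
    F <- diag(2) + matrix(stats::runif(4, -0.4, 0.4), 2L, 2L)
    if (det(F) > 0.3) return(F)
  }
}

fd_gradient <- function(f, x, eps = 1e-6) {
  g <- matrix(0, nrow(x), ncol(x))
  for (i in seq_len(nrow(x))) {
    for (k in seq_len(ncol(x))) {
      xp <- x; xp[i, k] <- xp[i, k] + eps
      xm <- x; xm[i, k] <- xm[i, k] - eps
      g[i, k] <- (f(xp) - f(xm)) / (2 * eps)
    }
  }
  g
}

# small structured square-grid mesh (exact h x h squares), for tests that
# need a mesh with machine-precision reference equilibrium
grid_mesh <- function(nx, ny, h = 1) {
  nodes <- as.matrix(expand.grid(x = (0:nx) * h, y = (0:ny) * h))
  id <- function(i, j) i + 1L + (nx + 1L) * j
  elements <- list()
  for (j in 0:(ny - 1L)) {
    for (i in 0:(nx - 1L)) {
      elements[[length(elements) + 1L]] <-
        c(id(i, j), id(i + 1L, j), id(i + 1L, j + 1L), id(i, j + 1L))
    }
  }
  poly_mesh(nodes, elements, "domain")
}
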