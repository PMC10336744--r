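# Global assembly: element operators -> constant sparse spring matrix plus
# grouped element tables for the area term; energies, gradients and tangents
# of the whole lattice. Degrees of freedom are stacked: dofs 1..N are the x
# coordinates, N+1..2N the y coordinates.

#' Assemble a lattice system from a mesh and materials
#'
#' Builds one [element_operator()] per element (Wachspress gradient matrix,
#' reference area, springs) and the constant global spring matrix
#' `L = sum_e mu_e M_e`. Identically shaped elements (the interior grid
#' squares of image meshes) share a cached M. The area (J) term bookkeeping
#' is grouped by polygon size so global energies/gradients/tangents evaluate
#' vectorized.
#'
#' @param mesh A [poly_mesh()].
#' @param materials Named list of [material()], one entry per region label
#'   present in the mesh.
#' @param rule_order Quadrature order for the gradient matrices (default 2).
#' @param volumetric_form `"compensated"` (default) or `"pure_quadratic"`,
#'   see [element_energy_J()].
#' @param quad_refine Fan subdivision level of the quadrature (default 2),
#'   see [polygon_quadrature()].
#' @return Object of class `lattice_system`.
#' @export
assemble <- function(mesh, materials, rule_order = 2L,
                     volumetric_form = c("compensated", "pure_quadratic"),
                     quad_refine = 2L) {
  volumetric_form <- match.arg(volumetric_form)
  regions <- unique(mesh$regions)
  missing <- setdiff(regions, names(materials))
  if (length(missing)) {
    stop("no material supplied for region(s): ", paste(missing, collapse = ", "))
  }
  N <- nrow(mesh$nodes)
  ne <- length(mesh$elements)
  mu_e <- vapply(mesh$regions, function(r) materials[[r]]$mu, numeric(1L),
                 USE.NAMES = FALSE)
  K_e <- vapply(mesh$regions, function(r) materials[[r]]$K, numeric(1L),
                USE.NAMES = FALSE)

  cache <- new.env(hash = TRUE, parent = emptyenv())
  ops <- vector("list", ne)
  ti <- vector("list", ne); tj <- vector("list", ne); tv <- vector("list", ne)
  A0 <- numeric(ne)
  for (e in seq_len(ne)) {
    el <- mesh$elements[[e]]
    v <- mesh$nodes[el, , drop = FALSE]
    poly <- convex_polygon(v)
    # translation-invariant shape key; cache hits for identical grid squares
    rel <- sweep(v, 2L, v[1L, ])
    key <- paste0(poly$n, ":", paste(round(rel / poly$scale * 1e8), collapse = ","))
    M <- cache[[key]]
    if (is.null(M)) {
      M <- grad_stiffness_matrix(poly,
                                 polygon_quadrature(poly, rule_order, quad_refine))
      cache[[key]] <- M
    }
    ops[[e]] <- structure(list(node_indices = el, n = poly$n, A0 = poly$area,
                               mu = mu_e[e], M = M, X = v,
                               region = mesh$regions[e]),
                          class = "element_operator")
    A0[e] <- poly$area
    n <- poly$n
    ti[[e]] <- rep(el, times = n)
    tj[[e]] <- rep(el, each = n)
    tv[[e]] <- as.vector(mu_e[e] * M)
  }
  L <- Matrix::sparseMatrix(i = unlist(ti), j = unlist(tj), x = unlist(tv),
                            dims = c(N, N))

  # group elements by vertex count for vectorized area-term evaluation
  ns <- lengths(mesh$elements)
  groups <- lapply(split(seq_len(ne), ns), function(ix) {
    n <- length(mesh$elements[[ix[1L]]])
    list(n = n,
         elem = ix,
         idx = matrix(unlist(mesh$elements[ix]), nrow = length(ix),
                      ncol = n, byrow = TRUE),
         A0 = A0[ix], mu = mu_e[ix], K = K_e[ix])
  })

  structure(list(mesh = mesh, ops = ops, L = L, groups = groups, N = N,
                 materials = materials, rule_order = rule_order,
                 volumetric_form = volumetric_form,
                 e_offset = sum(mu_e * A0), A0 = A0),
            class = "lattice_system")
}

#' @export
print.lattice_system <- function(x, ...) {
  cat(sprintf("<lattice_system> %d nodes, %d elements, volumetric form '%s'\n",
              x$N, length(x$ops), x$volumetric_form))
  invisible(x)
}

# Per-group deformed areas and chain-rule factors. x is the N x 2 coordinate
# matrix.
#' @noRd
group_areas <- function(g, x) {
  n <- g$n
  ip1 <- c(seq_len(n)[-1L], 1L)
  X <- matrix(x[g$idx, 1L], nrow = nrow(g$idx))
  Y <- matrix(x[g$idx, 2L], nrow = nrow(g$idx))
  Xp <- X[, ip1, drop = FALSE]; Yp <- Y[, ip1, drop = FALSE]
  A <- 0.5 * rowSums(X * Yp - Xp * Y)
  list(X = X, Y = Y, A = A)
}

#' Per-element deformed areas
#' @param sys A [assemble()]d lattice system.
#' @param x N x 2 matrix of deformed node coordinates.
#' @return Numeric vector of signed element areas, in element order.
#' @export
element_areas <- function(sys, x) {
  out <- numeric(length(sys$ops))
  for (g in sys$groups) out[g$elem] <- group_areas(g, x)$A
  out
}

#' Total potential (strain) energy of the lattice
#'
#' Returns `Inf` when any element is inverted (A <= 0), which the solver's
#' line search treats as an inadmissible state.
#'
#' @param sys A [assemble()]d lattice system.
#' @param x N x 2 matrix of deformed node coordinates.
#' @return Energy (kPa mm^2 per unit thickness).
#' @export
global_energy <- function(sys, x) {
  e <- 0.5 * (sum(x[, 1L] * (sys$L %*% x[, 1L])) +
                sum(x[, 2L] * (sys$L %*% x[, 2L]))) - sys$e_offset
  for (g in sys$groups) {
    A <- group_areas(g, x)$A
    if (any(A <= 0)) return(Inf)
    dA <- A - g$A0
    e <- e + sum(0.5 * g$K * dA^2 / g$A0)
    if (sys$volumetric_form == "compensated") e <- e - sum(g$mu * dA)
  }
  as.numeric(e)
}

# accumulate vals into vec at (possibly repeated) indices
#' @noRd
acc_at <- function(vec, idx, vals) {
  r <- rowsum(vals, idx)
  at <- as.integer(rownames(r))
  vec[at] <- vec[at] + r[, 1L]
  vec
}

#' Gradient of the lattice energy
#'
#' @inheritParams global_energy
#' @return N x 2 matrix of energy gradients with respect to node coordinates
#'   (kPa mm per unit thickness).
#' @export
global_gradient <- function(sys, x) {
  gx <- as.numeric(sys$L %*% x[, 1L])
  gy <- as.numeric(sys$L %*% x[, 2L])
  for (g in sys$groups) {
    n <- g$n
    ip1 <- c(seq_len(n)[-1L], 1L)
    im1 <- c(n, seq_len(n - 1L))
    ga <- group_areas(g, x)
    dUdA <- g$K * (ga$A - g$A0) / g$A0
    if (sys$volumetric_form == "compensated") dUdA <- dUdA - g$mu
    gAx <- 0.5 * (ga$Y[, ip1, drop = FALSE] - ga$Y[, im1, drop = FALSE])
    gAy <- 0.5 * (ga$X[, im1, drop = FALSE] - ga$X[, ip1, drop = FALSE])
    gx <- acc_at(gx, as.vector(g$idx), as.vector(dUdA * gAx))
    gy <- acc_at(gy, as.vector(g$idx), as.vector(dUdA * gAy))
  }
  cbind(gx, gy, deparse.level = 0L)
}

#' Tangent stiffness of the lattice
#'
#' Sparse symmetric `2N x 2N` matrix in stacked dof ordering (x block then
#' y block). The spring part is constant; the area part contributes a
#' rank-one block per element plus the shoelace curvature.
#'
#' @inheritParams global_energy
#' @return A `dgCMatrix`.
#' @export
global_tangent <- function(sys, x) {
  N <- sys$N
  Ls <- Matrix::summary(sys$L)
  ti <- list(c(Ls$i, Ls$i + N)); tj <- list(c(Ls$j, Ls$j + N))
  tv <- list(c(Ls$x, Ls$x))
  for (g in sys$groups) {
    n <- g$n
    m <- nrow(g$idx)
    ip1 <- c(seq_len(n)[-1L], 1L)
    im1 <- c(n, seq_len(n - 1L))
    ga <- group_areas(g, x)
    dUdA <- g$K * (ga$A - g$A0) / g$A0
    if (sys$volumetric_form == "compensated") dUdA <- dUdA - g$mu
    d2 <- g$K / g$A0
    gAx <- 0.5 * (ga$Y[, ip1, drop = FALSE] - ga$Y[, im1, drop = FALSE])
    gAy <- 0.5 * (ga$X[, im1, drop = FALSE] - ga$X[, ip1, drop = FALSE])
    G <- sqrt(d2) * cbind(gAx, gAy)          # m x 2n, scaled area gradients
    DOF <- cbind(g$idx, g$idx + N)           # m x 2n
    p <- 2L * n
    ra <- rep(seq_len(p), times = p); rb <- rep(seq_len(p), each = p)
    ti[[length(ti) + 1L]] <- as.vector(DOF[, ra])
    tj[[length(tj) + 1L]] <- as.vector(DOF[, rb])
    tv[[length(tv) + 1L]] <- as.vector(G[, ra, drop = FALSE] * G[, rb, drop = FALSE])
    # shoelace curvature, symmetric pairs
    hv <- 0.5 * dUdA
    for (a in seq_len(n)) {
      ia <- g$idx[, a]
      jn <- g$idx[, ip1[a]] + N
      jp <- g$idx[, im1[a]] + N
      ti[[length(ti) + 1L]] <- c(ia, ia, jn, jp)
      tj[[length(tj) + 1L]] <- c(jn, jp, ia, ia)
      tv[[length(tv) + 1L]] <- c(hv, -hv, hv, -hv)
    }
  }
  Matrix::sparseMatrix(i = unlist(ti), j = unlist(tj), x = unlist(tv),
                       dims = c(2L * N, 2L * N))
}
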