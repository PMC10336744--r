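# Quasi-static equilibrium by incremental energy minimization: load stepping,
# Newton iterations on the free coordinates with a backtracking line search
# that enforces energy decrease and element admissibility (all areas > 0),
# Dirichlet conditions imposed by elimination, dead traction loads lumped to
# the nodes of the reference boundary edges.

#' Dirichlet (displacement) boundary condition
#'
#' @param where Node selector: a predicate function `f(nodes) -> logical`, or
#'   one of the strings `"x==min"`, `"x==max"`, `"y==min"`, `"y==max"`,
#'   `"x==<value>"`, `"y==<value>"` (matched within `1e-6` of the mesh
#'   diameter).
#' @param u Prescribed displacement at full load (mm), length 2; use `NA` for
#'   a component left free (e.g. `c(NA, 10)` pulls vertically and leaves the
#'   horizontal component free). The displacement is ramped linearly with the
#'   load factor.
#' @return Object of class `polylat_bc`.
#' @export
bc_dirichlet <- function(where, u = c(0, 0)) {
  structure(list(type = "dirichlet", where = where, u = u),
            class = "polylat_bc")
}

#' Traction (dead-load) boundary condition
#'
#' A constant traction vector applied to the selected reference boundary
#' edges (dead load: defined on the reference geometry, not following the
#' deformation), ramped linearly with the load factor.
#'
#' @param where Edge selector: predicate on nodes as in [bc_dirichlet()];
#'   an edge is selected when both endpoints satisfy it.
#' @param traction_kPa Length-2 traction vector (kPa).
#' @return Object of class `polylat_bc`.
#' @export
bc_traction <- function(where, traction_kPa) {
  structure(list(type = "traction", where = where,
                 traction = as.numeric(traction_kPa)),
            class = "polylat_bc")
}

#' @noRd
select_nodes <- function(mesh, where) {
  nodes <- mesh$nodes
  if (is.function(where)) {
    sel <- where(nodes)
  } else if (is.character(where)) {
    m <- regmatches(where, regexec("^([xy])==(min|max|[-0-9.eE+]+)$", where))[[1L]]
    if (length(m) != 3L) stop("unrecognized node selector: ", where)
    col <- if (m[2L] == "x") 1L else 2L
    val <- switch(m[3L], min = min(nodes[, col]), max = max(nodes[, col]),
                  as.numeric(m[3L]))
    diam <- max(apply(nodes, 2L, function(v) diff(range(v))))
    sel <- abs(nodes[, col] - val) <= 1e-6 * diam
  } else {
    stop("node selector must be a function or a string")
  }
  if (!any(sel)) stop("boundary-condition selector matched no nodes")
  which(sel)
}

#' Consistent nodal loads of an edge traction
#'
#' Trapezoidal lumping of a constant traction on the selected reference
#' boundary edges: each edge of reference length L contributes `t * L / 2` to
#' each endpoint, so the total applied force is exactly `t * sum(L)`.
#'
#' @param mesh A [poly_mesh()].
#' @param bc A [bc_traction()].
#' @return N x 2 matrix of nodal forces (kPa mm per unit thickness).
#' @export
consistent_edge_loads <- function(mesh, bc) {
  sel <- select_nodes(mesh, bc$where)
  be <- boundary_edges(mesh)
  onsel <- be$a %in% sel & be$b %in% sel
  if (!any(onsel)) stop("traction selector matched no boundary edges")
  be <- be[onsel, ]
  FF <- matrix(0, nrow(mesh$nodes), 2L)
  L <- sqrt(rowSums((mesh$nodes[be$b, , drop = FALSE] -
                       mesh$nodes[be$a, , drop = FALSE])^2))
  for (i in seq_along(L)) {
    FF[be$a[i], ] <- FF[be$a[i], ] + bc$traction * L[i] / 2
    FF[be$b[i], ] <- FF[be$b[i], ] + bc$traction * L[i] / 2
  }
  FF
}

#' Solver configuration
#'
#' @param steps Number of load steps (default 20).
#' @param tol Newton tolerance on the max nodal residual (kPa mm); default
#'   `1e-8 * mu_max * h_mean`, computed at solve time when `NULL`.
#' @param max_newton Max Newton iterations per load step (default 50).
#' @param ls_beta Backtracking factor of the line search (default 0.5).
#' @param rule_order Quadrature order (default 2).
#' @param quad_refine Quadrature fan subdivision level (default 2).
#' @param max_bisect Max load-step bisections on failure (default 5).
#' @param volumetric_form See [element_energy_J()].
#' @param verbose Print one line per accepted load step.
#' @return List of class `solve_config`.
#' @export
solve_config <- function(steps = 20L, tol = NULL, max_newton = 50L,
                         ls_beta = 0.5, rule_order = 2L, quad_refine = 2L,
                         max_bisect = 5L, volumetric_form = "compensated",
                         verbose = FALSE) {
  stopifnot(steps >= 1L, max_newton >= 1L, ls_beta > 0, ls_beta < 1,
            max_bisect >= 0L)
  structure(list(steps = as.integer(steps), tol = tol,
                 max_newton = as.integer(max_newton), ls_beta = ls_beta,
                 rule_order = as.integer(rule_order),
                 quad_refine = as.integer(quad_refine),
                 max_bisect = as.integer(max_bisect),
                 volumetric_form = volumetric_form,
                 verbose = isTRUE(verbose)),
            class = "solve_config")
}

#' Quasi-static solve of the lattice under boundary conditions
#'
#' Ramps the load factor from 0 to 1 in `config$steps` increments. At each
#' step the Dirichlet values are imposed by elimination and the total
#' potential (strain energy minus dead-load work) is minimized over the free
#' coordinates by Newton iteration with a backtracking line search that
#' requires an energy decrease and keeps every element area positive. An
#' indefinite tangent factorization falls back to a gradient step. A step
#' that fails to converge is bisected up to `config$max_bisect` times; on
#' final failure the last stable state is returned with `converged = FALSE`.
#'
#' @param mesh A [poly_mesh()].
#' @param materials Named list of [material()] per region.
#' @param bcs List of [bc_dirichlet()] / [bc_traction()] objects.
#' @param config A [solve_config()].
#' @return Object of class `solve_result` with fields `u` (N x 2 nodal
#'   displacements, mm), `x` (deformed coordinates), `converged`, `energy`
#'   (per accepted load step), `t` (accepted load factors), `J` (per-element
#'   area ratios A/A0), `reactions` (N x 2, nonzero on constrained dofs),
#'   `residual`, and `provenance`.
#' @export
solve_static <- function(mesh, materials, bcs, config = solve_config()) {
  sys <- assemble(mesh, materials, config$rule_order, config$volumetric_form,
                  quad_refine = config$quad_refine)
  N <- sys$N
  X <- mesh$nodes
  fixed <- rep(FALSE, 2L * N)
  utar <- numeric(2L * N)
  F1 <- matrix(0, N, 2L)
  for (bc in bcs) {
    if (bc$type == "dirichlet") {
      sel <- select_nodes(mesh, bc$where)
      if (!is.na(bc$u[1L])) {
        fixed[sel] <- TRUE
        utar[sel] <- bc$u[1L]
      }
      if (!is.na(bc$u[2L])) {
        fixed[N + sel] <- TRUE
        utar[N + sel] <- bc$u[2L]
      }
    } else {
      F1 <- F1 + consistent_edge_loads(mesh, bc)
    }
  }
  free <- which(!fixed)
  f1 <- c(F1[, 1L], F1[, 2L])
  mu_max <- max(vapply(materials, function(m) m$mu, numeric(1L)))
  h_mean <- mean(sqrt(sys$A0))
  tol <- if (is.null(config$tol)) 1e-8 * mu_max * h_mean else config$tol

  xv <- c(X[, 1L], X[, 2L])
  Xv <- c(X[, 1L], X[, 2L])

  res_norm <- function(gfull) {
    g <- gfull
    g[fixed] <- 0
    max(sqrt(g[seq_len(N)]^2 + g[N + seq_len(N)]^2))
  }
  potential <- function(xv, t) {
    x <- cbind(xv[seq_len(N)], xv[N + seq_len(N)])
    global_energy(sys, x) - t * sum(f1 * xv)
  }

  # Solve K (shifted to SPD when needed) d = rhs; NULL when no usable
  # direction. The tangent's sparsity pattern is constant for a given mesh
  # and constraint set, so the symbolic factorization is computed once and
  # the numeric factor updated in place (Matrix::update with an identity
  # multiple as the modified-Newton shift); this also keeps the CHOLMOD
  # workspace from being reallocated every iteration.
  chol_cache <- NULL
  spd_solve <- function(Kff, rhs, require_descent = NULL) {
    dscale <- mean(Matrix::diag(Kff))
    # escalate fast towards the Gershgorin bound, which guarantees strict
    # diagonal dominance (failed indefinite factorizations are wasted work)
    gersh <- 1.1 * max(Matrix::rowSums(abs(Kff)))
    taus <- c(0, 1e-6 * dscale, 1e-3 * dscale, 0.1 * dscale, dscale, gersh)
    for (tau in taus) {
      fac <- tryCatch({
        if (is.null(chol_cache)) {
          chol_cache <<- Matrix::Cholesky(Kff, LDL = FALSE, perm = TRUE,
                                          Imult = tau)
        } else {
          chol_cache <<- Matrix::update(chol_cache, Kff, mult = tau)
        }
        chol_cache
      }, error = function(e) NULL, warning = function(w) NULL)
      if (!is.null(fac)) {
        dd <- as.numeric(Matrix::solve(fac, rhs))
        ok <- all(is.finite(dd))
        if (ok && !is.null(require_descent)) {
          ok <- sum(require_descent * dd) < 0
        }
        if (ok) return(dd)
      }
    }
    NULL
  }

  newton_at <- function(t, xv, t_from = NULL) {
    # linear predictor: instead of jolting only the constrained nodes by the
    # full Dirichlet increment (which badly distorts the boundary elements on
    # fine meshes), solve the tangent system at the current state for the
    # interior response to the increment, then Newton-correct
    du_fix <- (Xv[fixed] + t * utar[fixed]) - xv[fixed]
    if (!is.null(t_from) && any(du_fix != 0)) {
      x <- cbind(xv[seq_len(N)], xv[N + seq_len(N)])
      K <- global_tangent(sys, x)
      rhs <- -as.numeric(K[free, fixed, drop = FALSE] %*% du_fix) +
        (t - t_from) * f1[free]
      d <- spd_solve(Matrix::forceSymmetric(K[free, free, drop = FALSE]), rhs)
      if (!is.null(d)) {
        xtry <- xv
        xtry[fixed] <- xv[fixed] + du_fix
        xtry[free] <- xv[free] + d
        if (is.finite(potential(xtry, t))) xv <- xtry
      }
    }
    xv[fixed] <- Xv[fixed] + t * utar[fixed]
    for (it in seq_len(config$max_newton)) {
      x <- cbind(xv[seq_len(N)], xv[N + seq_len(N)])
      g2 <- global_gradient(sys, x)
      gfull <- c(g2[, 1L], g2[, 2L]) - t * f1
      r <- res_norm(gfull)
      if (r <= tol) {
        return(list(ok = TRUE, xv = xv, residual = r, iterations = it - 1L))
      }
      K <- global_tangent(sys, x)
      gf <- gfull[free]
      # modified Newton: an indefinite factorization escalates a diagonal
      # shift until the shifted tangent is SPD and gives a descent direction
      d <- spd_solve(Matrix::forceSymmetric(K[free, free, drop = FALSE]),
                     -gf, require_descent = gf)
      if (is.null(d)) {
        d <- -gf * (h_mean / (mu_max + max(abs(gf))))  # steepest descent
      }
      e0 <- potential(xv, t)
      alpha <- 1
      accepted <- FALSE
      slope <- sum(gf * d)
      for (ls in 1:60) {
        xtry <- xv
        xtry[free] <- xv[free] + alpha * d
        e1 <- potential(xtry, t)
        if (is.finite(e1) && e1 <= e0 + 1e-4 * alpha * slope) {
          xv <- xtry
          accepted <- TRUE
          break
        }
        alpha <- alpha * config$ls_beta
      }
      if (!accepted) {
        return(list(ok = FALSE, xv = xv, residual = r, iterations = it))
      }
    }
    list(ok = FALSE, xv = xv, residual = r, iterations = config$max_newton)
  }

  targets <- seq_len(config$steps) / config$steps
  t_cur <- 0
  energy <- numeric(0L)
  t_acc <- numeric(0L)
  converged <- TRUE
  for (tk in targets) {
    t_lo <- t_cur
    t_hi <- tk
    nb <- 0L
    while (t_cur < tk - 1e-12) {
      st <- newton_at(t_hi, xv, t_cur)
      if (st$ok) {
        xv <- st$xv
        t_cur <- t_hi
        energy <- c(energy, potential(xv, t_cur))
        t_acc <- c(t_acc, t_cur)
        if (config$verbose) {
          message(sprintf("  t = %.4f: %d Newton iteration(s), residual %.3g",
                          t_cur, st$iterations, st$residual))
        }
        t_hi <- tk
      } else {
        nb <- nb + 1L
        if (nb > config$max_bisect) {
          converged <- FALSE
          break
        }
        t_hi <- (t_cur + t_hi) / 2
      }
    }
    if (!converged) break
  }

  x <- cbind(xv[seq_len(N)], xv[N + seq_len(N)])
  g2 <- global_gradient(sys, x)
  gfull <- c(g2[, 1L], g2[, 2L]) - t_cur * f1
  reactions <- matrix(0, N, 2L)
  reactions[fixed[seq_len(N)], 1L] <- gfull[seq_len(N)][fixed[seq_len(N)]]
  reactions[fixed[N + seq_len(N)], 2L] <- gfull[N + seq_len(N)][fixed[N + seq_len(N)]]
  J <- element_areas(sys, x) / sys$A0
  structure(list(u = x - X, x = x, converged = converged,
                 energy = energy, t = t_acc, t_final = t_cur, J = J,
                 reactions = reactions, residual = res_norm(gfull),
                 system = sys,
                 provenance = list(config = config,
                                   n_nodes = N,
                                   n_elements = length(sys$ops),
                                   mesh_checksum = sum(mesh$nodes) +
                                     sum(unlist(mesh$elements)))),
            class = "solve_result")
}

#' @export
print.solve_result <- function(x, ...) {
  cat(sprintf(paste0("<solve_result> converged = %s at t = %.3f, ",
                     "max |u| = %.4g mm, J in [%.4f, %.4f]\n"),
              x$converged, x$t_final, max(sqrt(rowSums(x$u^2))),
              min(x$J), max(x$J)))
  invisible(x)
}

#' Interpolate a nodal field at arbitrary points
#'
#' Locates each query point in the mesh (nearest-centroid candidate search,
#' exact convex containment test) and interpolates with the element's
#' Wachspress shape functions. Points marginally outside the mesh (boundary
#' round-off) use the nearest element.
#'
#' @param mesh A [poly_mesh()].
#' @param field N x k nodal values.
#' @param pts m x 2 query points (mm).
#' @return m x k matrix of interpolated values.
#' @export
interpolate_field <- function(mesh, field, pts) {
  field <- as.matrix(field)
  if (is.null(dim(pts))) pts <- matrix(pts, ncol = 2L)
  cen <- element_centroids(mesh)
  ne <- nrow(cen)
  rad <- numeric(ne)
  for (e in seq_len(ne)) {
    v <- mesh_element_vertices(mesh, e)
    rad[e] <- sqrt(max((v[, 1L] - cen[e, 1L])^2 + (v[, 2L] - cen[e, 2L])^2))
  }
  binsize <- 2 * max(rad)
  bx <- floor(cen[, 1L] / binsize); by <- floor(cen[, 2L] / binsize)
  bkey <- paste0(bx, "_", by)
  bins <- split(seq_len(ne), bkey)
  out <- matrix(NA_real_, nrow(pts), ncol(field))
  for (q in seq_len(nrow(pts))) {
    p <- pts[q, ]
    qx <- floor(p[1L] / binsize); qy <- floor(p[2L] / binsize)
    cand <- integer(0L)
    for (dx in -1:1) for (dy in -1:1) {
      cand <- c(cand, bins[[paste0(qx + dx, "_", qy + dy)]])
    }
    if (!length(cand)) cand <- seq_len(ne)
    d2 <- (cen[cand, 1L] - p[1L])^2 + (cen[cand, 2L] - p[2L])^2
    cand <- cand[order(d2)]
    chosen <- 0L
    for (e in cand) {
      v <- mesh_element_vertices(mesh, e)
      ex <- c(v[-1L, 1L], v[1L, 1L]) - v[, 1L]
      ey <- c(v[-1L, 2L], v[1L, 2L]) - v[, 2L]
      crs <- ex * (p[2L] - v[, 2L]) - ey * (p[1L] - v[, 1L])
      if (all(crs >= -1e-9 * max(ex^2 + ey^2))) {
        chosen <- e
        break
      }
    }
    if (!chosen) chosen <- cand[1L]
    el <- mesh$elements[[chosen]]
    poly <- convex_polygon(mesh$nodes[el, , drop = FALSE])
    w <- tryCatch(wachspress_values(poly, p), error = function(e) NULL)
    if (is.null(w)) {
      # nearest vertex fallback for points outside the closure
      v <- mesh$nodes[el, , drop = FALSE]
      w <- numeric(poly$n)
      w[which.min((v[, 1L] - p[1L])^2 + (v[, 2L] - p[2L])^2)] <- 1
    }
    out[q, ] <- crossprod(field[el, , drop = FALSE], w)
  }
  out
}

#' Mesh-refinement convergence study of the uniaxial tension benchmark
#'
#' Solves the clamped uniaxial tension benchmark (rectangular sample, bottom
#' boundary fixed, top boundary displaced vertically with the horizontal
#' component gripped) on a ladder of centroidal-Voronoi meshes plus a
#' `ref_factor` times finer reference mesh, measures the L2 norm of the
#' displacement difference sampled at the coarse nodes, and fits the
#' convergence order as the least-squares slope of log(error) against
#' log(h), h = sqrt(domain area / n).
#'
#' @param ns Element counts of the refinement ladder (>= 3 sizes).
#' @param ref_factor Reference mesh is `ref_factor * max(ns)` elements.
#' @param seed RNG seed for all meshes.
#' @param domain Benchmark domain (default the 20 x 10 mm rectangle).
#' @param stretch_mm Prescribed top displacement (default 10 mm).
#' @param materials Material map (default mu = 1, K = 100 kPa).
#' @param lloyd_iters Lloyd iterations per mesh (default 30).
#' @param config Solver configuration (default 10 load steps).
#' @return List with `order` (fitted slope), `table` (n, h, error), and
#'   `ref_n`. Non-converged ladder members are excluded and flagged in
#'   `table$converged`.
#' @export
convergence_study <- function(ns = c(100L, 400L, 1600L), ref_factor = 4L,
                              seed = 1L, domain = domain_rectangle(20, 10),
                              stretch_mm = 10,
                              materials = list(domain = material(1, 100)),
                              lloyd_iters = 30L,
                              config = solve_config(steps = 10L)) {
  if (length(ns) < 3L) stop("need at least 3 mesh sizes")
  bcs <- list(bc_dirichlet("y==min", c(0, 0)),
              bc_dirichlet("y==max", c(0, stretch_mm)))
  run <- function(n) {
    mesh <- cvt_polygonal_mesh(domain, n, iterations = lloyd_iters, seed = seed)
    sol <- solve_static(mesh, materials, bcs, config)
    list(mesh = mesh, sol = sol)
  }
  ref_n <- as.integer(max(ns) * ref_factor)
  ref <- run(ref_n)
  tab <- data.frame(n = ns, h = sqrt(domain$area / ns), error = NA_real_,
                    converged = FALSE)
  for (i in seq_along(ns)) {
    r <- run(ns[i])
    tab$converged[i] <- r$sol$converged
    if (!r$sol$converged) next
    uref <- interpolate_field(ref$mesh, ref$sol$u, r$mesh$nodes)
    du <- r$sol$u - uref
    tab$error[i] <- sqrt(mean(rowSums(du^2)))
  }
  ok <- tab$converged & is.finite(tab$error)
  if (sum(ok) < 2L) stop("too few converged ladder members to fit an order")
  fit <- stats::lm(log(error) ~ log(h), data = tab[ok, ])
  list(order = unname(stats::coef(fit)[2L]), table = tab, ref_n = ref_n,
       ref_converged = ref$sol$converged, seed = seed)
}
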