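# Programmatic benchmark fixtures: every benchmark input is generated in
# code (no downloads), bit-reproducible from its parameters and seed.

#' Reference material set for the benchmarks
#'
#' Matrix mu = 1 kPa, K = 100 kPa; soft inclusion one tenth of the matrix
#' (mu = 0.1, K = 10); hard inclusion ten times the matrix (mu = 10,
#' K = 1000).
#'
#' @return Named list of [material()]: `matrix`, `soft`, `hard`.
#' @export
benchmark_materials <- function() {
  list(matrix = material(1, 100),
       soft = material(0.1, 10),
       hard = material(10, 1000))
}

# rasterize: label 1 where predicate(true) on pixel centers
#' @noRd
rasterize_image <- function(width, height, resolution, predicate) {
  nx <- round(width * resolution); ny <- round(height * resolution)
  ps <- 1 / resolution
  xc <- ((seq_len(nx)) - 0.5) * ps
  yc <- ((seq_len(ny)) - 0.5) * ps
  lab <- matrix(0L, nx, ny)
  lab[predicate(matrix(rep(xc, times = ny), nx, ny),
                matrix(rep(yc, each = nx), nx, ny))] <- 1L
  label_image(lab, ps)
}

#' Composite sample image with circular inclusions
#'
#' A rectangle (default 60 x 100 mm) of matrix phase (label 0) containing
#' circular inclusions (label 1) of the given radius. The default layout is
#' 16 circles of radius 4 mm on a regular 4 x 4 grid centered in the sample
#' (15 mm horizontal and 25 mm vertical pitch, first row/column inset half a
#' pitch). Circles must lie strictly inside the sample and be pairwise
#' disjoint.
#'
#' @param width,height Sample size (mm).
#' @param radius Inclusion radius (mm).
#' @param centers k x 2 matrix of circle centers (mm); NULL for the default
#'   4 x 4 layout. `k = 0` rows give a uniform single-label image.
#' @param resolution Pixels per mm (default 10).
#' @return A [label_image()] with attribute `centers`.
#' @export
make_composite_image <- function(width = 60, height = 100, radius = 4,
                                 centers = NULL, resolution = 10) {
  if (is.null(centers)) {
    cx <- width / 8 + (0:3) * width / 4
    cy <- height / 8 + (0:3) * height / 4
    centers <- cbind(rep(cx, times = 4L), rep(cy, each = 4L))
  }
  centers <- matrix(as.numeric(centers), ncol = 2L)
  k <- nrow(centers)
  if (k) {
    if (any(centers[, 1L] - radius <= 0 | centers[, 1L] + radius >= width |
              centers[, 2L] - radius <= 0 | centers[, 2L] + radius >= height)) {
      stop("circles must lie strictly inside the sample")
    }
    if (k > 1L) {
      d <- as.matrix(stats::dist(centers))
      diag(d) <- Inf
      if (min(d) <= 2 * radius) stop("circles must be pairwise disjoint")
    }
  }
  img <- rasterize_image(width, height, resolution, function(X, Y) {
    inside <- matrix(FALSE, nrow(X), ncol(X))
    for (i in seq_len(k)) {
      inside <- inside | ((X - centers[i, 1L])^2 + (Y - centers[i, 2L])^2 <=
                            radius^2)
    }
    inside
  })
  attr(img, "centers") <- centers
  attr(img, "radius") <- radius
  img
}

#' Bilayer image with a sinusoidal interface
#'
#' Label 1 above the interface `y = mean_height + amplitude *
#' sin(2 pi x / wavelength)`, label 0 below. Defaults: a 20 x 10 mm sample,
#' amplitude 2 mm, one full period across the width, interface mean at
#' mid-height.
#'
#' @param width,height Sample size (mm).
#' @param amplitude Interface amplitude (mm).
#' @param wavelength Interface wavelength (mm).
#' @param mean_height Mean interface height (mm).
#' @param resolution Pixels per mm (default 10).
#' @return A [label_image()].
#' @export
make_bilayer_image <- function(width = 20, height = 10, amplitude = 2,
                               wavelength = 20, mean_height = height / 2,
                               resolution = 10) {
  if (mean_height - amplitude <= 0 || mean_height + amplitude >= height) {
    stop("interface exits the sample: reduce amplitude or recenter")
  }
  rasterize_image(width, height, resolution, function(X, Y) {
    Y > mean_height + amplitude * sin(2 * pi * X / wavelength)
  })
}

#' Circular-inclusion sample image
#'
#' A single circular inclusion (label 1) in a rectangular matrix (label 0).
#' Defaults place a 2.5 mm radius circle at the center of the 20 x 10 mm
#' benchmark rectangle.
#'
#' @param width,height Sample size (mm).
#' @param center Circle center (mm).
#' @param radius Circle radius (mm).
#' @param resolution Pixels per mm.
#' @return A [label_image()].
#' @export
make_circle_inclusion_image <- function(width = 20, height = 10,
                                        center = c(10, 5), radius = 2.5,
                                        resolution = 10) {
  make_composite_image(width, height, radius, matrix(center, 1L, 2L),
                       resolution)
}

#' Femur-like smooth blob image
#'
#' A synthetic stand-in for a segmented organ cross-section: a star-convex
#' blob whose radius is a seeded low-order Fourier perturbation of a base
#' radius, `r(theta) = r0 (1 + sum_k a_k cos(k theta + phi_k))`, k = 2..5,
#' |a_k| <= 0.08. The boundary is simple by construction and the enclosed
#' area has the closed form `pi r0^2 (1 + sum a_k^2 / 2)`, stored in the
#' `analytic_area_mm2` attribute.
#'
#' @param seed Integer RNG seed; a fixed seed reproduces the image exactly.
#' @param size_mm Image side length (mm).
#' @param resolution Pixels per mm.
#' @return A [label_image()] (blob label 1) with attributes
#'   `analytic_area_mm2` and `params`.
#' @export
make_femur_blob <- function(seed = 1L, size_mm = 40, resolution = 10) {
  set.seed(seed)
  r0 <- 0.3 * size_mm
  kmodes <- 2:5
  a <- stats::runif(length(kmodes), -0.08, 0.08)
  phi <- stats::runif(length(kmodes), 0, 2 * pi)
  cen <- c(size_mm / 2, size_mm / 2)
  img <- rasterize_image(size_mm, size_mm, resolution, function(X, Y) {
    th <- atan2(Y - cen[2L], X - cen[1L])
    r <- r0 * (1 + Reduce(`+`, lapply(seq_along(kmodes), function(i) {
      a[i] * cos(kmodes[i] * th + phi[i])
    })))
    (X - cen[1L])^2 + (Y - cen[2L])^2 <= r^2
  })
  attr(img, "analytic_area_mm2") <- pi * r0^2 * (1 + sum(a^2) / 2)
  attr(img, "params") <- list(seed = seed, r0 = r0, a = a, phi = phi,
                              center = cen)
  img
}

#' Run a named benchmark end to end
#'
#' Wires fixture generation, meshing, materials and the static solver for
#' the packaged benchmark problems and returns a structured report with the
#' invariant-checklist outcome (mesh conformity, deformed-area statistics,
#' reaction/load balance).
#'
#' @param name One of `"uniaxial"`, `"cook"`, `"circle_inclusion"`,
#'   `"bilayer"`, `"composite16"`, `"femur"`.
#' @param inclusion `"hard"` or `"soft"` (heterogeneous benchmarks).
#' @param mode `"tension"` or `"shear"` (composite benchmark).
#' @param disp Prescribed displacement magnitude (mm); benchmark default
#'   when NULL (uniaxial/inclusion/bilayer 10; composite tension 50, shear
#'   36; femur 8).
#' @param n_elements CVT element count for the homogeneous benchmarks.
#' @param h Lattice length for the image-based benchmarks (mm).
#' @param steps Load steps.
#' @param seed RNG seed (meshing / blob generation).
#' @param out_dir If non-NULL, write `mesh.vtk`, `result.vtk` and
#'   `report.json` there.
#' @return Report list (invisibly contains `solution` and `mesh`).
#' @export
run_benchmark <- function(name = c("uniaxial", "cook", "circle_inclusion",
                                   "bilayer", "composite16", "femur"),
                          inclusion = c("hard", "soft"),
                          mode = c("tension", "shear"), disp = NULL,
                          n_elements = 400L, h = NULL, steps = 20L,
                          seed = 1L, out_dir = NULL) {
  name <- match.arg(name)
  inclusion <- match.arg(inclusion)
  mode <- match.arg(mode)
  mats <- benchmark_materials()
  cfg <- solve_config(steps = steps)
  if (name == "uniaxial") {
    if (is.null(disp)) disp <- 10
    mesh <- cvt_polygonal_mesh(domain_rectangle(20, 10), n_elements,
                               iterations = 50L, seed = seed)
    materials <- list(domain = mats$matrix)
    bcs <- list(bc_dirichlet("y==min", c(0, 0)),
                bc_dirichlet("y==max", c(0, disp)))
  } else if (name == "cook") {
    mesh <- cvt_polygonal_mesh(cook_domain(), n_elements,
                               iterations = 50L, seed = seed)
    materials <- list(domain = mats$matrix)
    bcs <- list(bc_dirichlet("x==min", c(0, 0)),
                bc_traction("x==max", c(0, 1)))
  } else if (name == "circle_inclusion") {
    if (is.null(disp)) disp <- 10
    if (is.null(h)) h <- 1
    img <- make_circle_inclusion_image()
    mesh <- build_mesh_from_image(img, h, c(0L, 1L))
    materials <- list(`0` = mats$matrix, `1` = mats[[inclusion]])
    bcs <- list(bc_dirichlet("y==min", c(0, 0)),
                bc_dirichlet("y==max", c(0, disp)))
  } else if (name == "bilayer") {
    if (is.null(disp)) disp <- 10
    if (is.null(h)) h <- 1
    img <- make_bilayer_image()
    mesh <- build_mesh_from_image(img, h, c(0L, 1L))
    materials <- list(`0` = mats$matrix, `1` = mats[[inclusion]])
    bcs <- list(bc_dirichlet("y==min", c(0, 0)),
                bc_dirichlet("y==max", c(0, disp)))
  } else if (name == "composite16") {
    if (is.null(disp)) disp <- if (mode == "tension") 50 else 36
    if (is.null(h)) h <- 2
    img <- make_composite_image()
    mesh <- build_mesh_from_image(img, h, c(0L, 1L))
    materials <- list(`0` = mats$matrix, `1` = mats[[inclusion]])
    utop <- if (mode == "tension") c(0, disp) else c(disp, 0)
    bcs <- list(bc_dirichlet("y==min", c(0, 0)),
                bc_dirichlet("y==max", utop))
  } else {
    if (is.null(disp)) disp <- 8
    if (is.null(h)) h <- 2
    img <- make_femur_blob(seed = seed)
    mesh <- build_mesh_from_image(img, h, c(0L, 1L), keep = 1L)
    materials <- list(`1` = mats$matrix)
    ylim <- range(mesh$nodes[, 2L])
    band <- 0.1 * diff(ylim)
    bcs <- list(bc_dirichlet(function(nd) nd[, 2L] <= ylim[1L] + band, c(0, 0)),
                bc_dirichlet(function(nd) nd[, 2L] >= ylim[2L] - band,
                             c(disp, 0)))
  }
  sol <- solve_static(mesh, materials, bcs, cfg)
  loads <- Reduce(`+`, lapply(bcs, function(bc) {
    if (bc$type == "traction") consistent_edge_loads(mesh, bc) else 0
  }), accumulate = FALSE)
  total_load <- if (is.matrix(loads)) colSums(loads) * sol$t_final else c(0, 0)
  total_reaction <- colSums(sol$reactions)
  imbalance <- sqrt(sum((total_reaction + total_load)^2))
  # scale by the one-sided reaction magnitude: for pure-Dirichlet problems the
  # net reaction cancels between opposing boundaries
  scale_f <- max(sqrt(sum(total_load^2)),
                 0.5 * sum(sqrt(rowSums(sol$reactions^2))), 1e-30)
  per_phase <- lapply(split(seq_along(sol$J), mesh$regions), function(ix) {
    list(n_elements = length(ix),
         mean_abs_J_dev = mean(abs(sol$J[ix] - 1)),
         max_abs_J_dev = max(abs(sol$J[ix] - 1)))
  })
  report <- list(
    benchmark = name,
    n_nodes = nrow(mesh$nodes), n_elements = length(mesh$elements),
    converged = sol$converged, load_factor = sol$t_final,
    final_energy = if (length(sol$energy)) sol$energy[length(sol$energy)] else 0,
    max_abs_J_dev = max(abs(sol$J - 1)),
    per_phase = per_phase,
    total_applied_load = total_load,
    reaction_balance_rel_error = imbalance / scale_f,
    mesh_conforming = as.logical(mesh_is_conforming(mesh)),
    seed = seed)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_mesh_vtk(mesh, file.path(out_dir, "mesh.vtk"))
    write_mesh_vtk(mesh, file.path(out_dir, "result.vtk"),
                   point_data = list(displacement = sol$u),
                   cell_data = list(J = sol$J))
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(c(report, list(solution = sol, mesh = mesh)))
}
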