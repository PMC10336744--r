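# Centroidal Voronoi (Lloyd) polygonal meshing of convex benchmark domains:
# the fully polygonal meshes used for the homogeneous uniaxial-tension and
# Cook-membrane tests.

#' Rectangular domain
#' @param width,height Side lengths (mm).
#' @param origin Lower-left corner (mm).
#' @return Object of class `domain2d`.
#' @export
domain_rectangle <- function(width = 20, height = 10, origin = c(0, 0)) {
  v <- rbind(origin,
             origin + c(width, 0),
             origin + c(width, height),
             origin + c(0, height))
  structure(list(kind = "rectangle", boundary = v, area = width * height),
            class = "domain2d")
}

#' Cook membrane domain
#'
#' The standard tapered-panel bending/shear benchmark: the trapezoid with
#' corners (0,0), (48,44), (48,60), (0,44) mm. Left edge 44 mm (clamped in
#' the benchmark), right edge 16 mm (sheared), area 1440 mm^2.
#'
#' @return Object of class `domain2d`.
#' @export
cook_domain <- function() {
  v <- rbind(c(0, 0), c(48, 44), c(48, 60), c(0, 44))
  structure(list(kind = "cook_trapezoid", boundary = v,
                 area = polygon_area(v)),
            class = "domain2d")
}

#' Polygonal domain
#' @param vertices CCW boundary vertex matrix (mm); must be convex.
#' @return Object of class `domain2d`.
#' @export
domain_polygon <- function(vertices) {
  p <- convex_polygon(vertices)
  structure(list(kind = "polygonal", boundary = p$vertices, area = p$area),
            class = "domain2d")
}

#' @export
print.domain2d <- function(x, ...) {
  cat(sprintf("<domain2d> %s, area = %g mm^2\n", x$kind, x$area))
  invisible(x)
}

# Sutherland-Hodgman clip of a convex polygon against the half-plane
# n . x <= c. Returns a matrix (possibly with 0 rows).
#' @noRd
clip_halfplane <- function(v, nrm, cval) {
  f <- v[, 1L] * nrm[1L] + v[, 2L] * nrm[2L] - cval
  if (all(f <= 0)) return(v)
  if (all(f >= 0)) return(v[0L, , drop = FALSE])
  n <- nrow(v)
  out <- matrix(0, n + 2L, 2L)
  k <- 0L
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    fi <- f[i]; fj <- f[j]
    if (fi <= 0) {
      k <- k + 1L; out[k, ] <- v[i, ]
    }
    if ((fi < 0 && fj > 0) || (fi > 0 && fj < 0)) {
      t <- fi / (fi - fj)
      k <- k + 1L; out[k, ] <- v[i, ] + t * (v[j, ] - v[i, ])
    }
  }
  out[seq_len(k), , drop = FALSE]
}

# Bounded Voronoi cells of seeds S inside a convex domain polygon, clipping
# each cell against bisector half-planes of nearby seeds only (sorted by
# distance, stopping once half the seed distance exceeds the cell radius).
#' @noRd
voronoi_cells <- function(bnd, S) {
  n <- nrow(S)
  cells <- vector("list", n)
  if (n == 1L) {
    cells[[1L]] <- bnd
    return(cells)
  }
  area <- polygon_area(bnd)
  binsize <- 2 * sqrt(area / n)
  bx <- floor((S[, 1L] - min(S[, 1L])) / binsize)
  by <- floor((S[, 2L] - min(S[, 2L])) / binsize)
  nbx <- max(bx) + 1L
  bkey <- bx + by * nbx
  binlist <- split(seq_len(n), bkey)
  for (i in seq_len(n)) {
    # candidates from the 5x5 bin window; fall back to all seeds if the
    # security radius is not reached
    keys <- as.character(outer(bx[i] + (-2:2), (by[i] + (-2:2)) * nbx, "+"))
    cand <- unlist(binlist[keys], use.names = FALSE)
    cand <- cand[cand != i]
    window_r <- 2 * binsize
    repeat {
      cell <- clip_cell(bnd, S, i, cand)
      rmax <- sqrt(max((cell[, 1L] - S[i, 1L])^2 + (cell[, 2L] - S[i, 2L])^2))
      if (2 * rmax <= window_r || length(cand) == n - 1L) break
      cand <- seq_len(n)[-i]
      window_r <- Inf
    }
    cells[[i]] <- cell
  }
  cells
}

#' @noRd
clip_cell <- function(bnd, S, i, cand) {
  cell <- bnd
  if (!length(cand)) return(cell)
  d2 <- (S[cand, 1L] - S[i, 1L])^2 + (S[cand, 2L] - S[i, 2L])^2
  ord <- order(d2)
  rmax2 <- max((cell[, 1L] - S[i, 1L])^2 + (cell[, 2L] - S[i, 2L])^2)
  for (k in ord) {
    if (d2[k] > 4 * rmax2) break
    j <- cand[k]
    nrm <- S[j, ] - S[i, ]
    cval <- sum(nrm * (S[i, ] + S[j, ])) / 2
    cell <- clip_halfplane(cell, nrm, cval)
    if (nrow(cell) < 3L) stop("Voronoi cell collapsed; duplicate seeds?")
    rmax2 <- max((cell[, 1L] - S[i, 1L])^2 + (cell[, 2L] - S[i, 2L])^2)
  }
  cell
}

#' Lloyd-relaxed centroidal Voronoi polygonal mesh
#'
#' Samples `n_elements` seeds uniformly in the (convex) domain, then runs
#' Lloyd iterations: build the bounded Voronoi diagram (cells clipped exactly
#' against the domain boundary), move every seed to its cell centroid. All
#' cells are convex CCW polygons by construction and their areas sum to the
#' domain area.
#'
#' @param domain A [domain_rectangle()], [cook_domain()] or
#'   [domain_polygon()]; the boundary must be convex.
#' @param n_elements Number of Voronoi cells (>= 1).
#' @param iterations Lloyd iterations (default 100).
#' @param seed Integer RNG seed controlling seed placement.
#' @return A [poly_mesh()] with attributes `movement` (max seed-to-centroid
#'   distance per iteration, mm) and `seed`.
#' @export
cvt_polygonal_mesh <- function(domain, n_elements, iterations = 100L, seed = 1L) {
  if (n_elements < 1L) stop("n_elements must be >= 1")
  bnd <- convex_polygon(domain$boundary)$vertices
  bb <- apply(bnd, 2L, range)
  set.seed(seed)
  for (attempt in 1:3) {
    S <- matrix(0, 0L, 2L)
    while (nrow(S) < n_elements) {
      m <- 2L * (n_elements - nrow(S)) + 10L
      P <- cbind(stats::runif(m, bb[1L, 1L], bb[2L, 1L]),
                 stats::runif(m, bb[1L, 2L], bb[2L, 2L]))
      P <- P[point_in_polygon(P, bnd), , drop = FALSE]
      S <- rbind(S, P)
    }
    S <- S[seq_len(n_elements), , drop = FALSE]
    movement <- numeric(iterations)
    ok <- TRUE
    res <- tryCatch({
      for (it in seq_len(iterations)) {
        cells <- voronoi_cells(bnd, S)
        cents <- t(vapply(cells, polygon_centroid, numeric(2L)))
        movement[it] <- if (n_elements) sqrt(max(rowSums((cents - S)^2))) else 0
        S <- cents
      }
      voronoi_cells(bnd, S)
    }, error = function(e) e)
    if (!inherits(res, "error")) {
      cells <- res
      break
    }
    ok <- FALSE
    if (attempt == 3L) stop("CVT meshing failed after 3 reseeds: ",
                            conditionMessage(res))
  }
  # weld shared cell vertices into a conforming node set
  allv <- do.call(rbind, cells)
  tol <- 1e-7 * sqrt(domain$area / n_elements)
  mg <- merge_points(allv, tol)
  counts <- vapply(cells, nrow, integer(1L))
  stop_at <- cumsum(counts)
  elements <- vector("list", n_elements)
  for (i in seq_len(n_elements)) {
    ids <- mg$map[(stop_at[i] - counts[i] + 1L):stop_at[i]]
    # drop consecutive duplicates created by welding short edges
    keep <- ids != c(ids[-1L], ids[1L])
    elements[[i]] <- ids[keep]
  }
  mesh <- poly_mesh(mg$coords, elements, regions = "domain")
  attr(mesh, "movement") <- movement
  attr(mesh, "seed") <- seed
  mesh
}
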