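# Planar geometry primitives shared by the shape-function, meshing and solver
# layers. All coordinates are physical (mm); polygons are stored as n x 2
# matrices of vertices in counter-clockwise (CCW) order without a repeated
# closing vertex.

#' Rotate a 2-vector by +90 degrees
#' @noRd
perp2 <- function(v) c(-v[2L], v[1L])

#' Signed area of a triangle
#'
#' Computes half the cross product `(m - l) x (p - l)`. The sign is positive
#' when the triple `(l, m, p)` winds counter-clockwise, negative when it winds
#' clockwise, and zero for collinear points. This is the elementary building
#' block of the Wachspress weight functions.
#'
#' @param l,m,p Numeric length-2 vectors, vertex coordinates in mm.
#' @return Signed triangle area in mm^2.
#' @examples
#' signed_triangle_area(c(0, 0), c(1, 0), c(0, 1)) # 0.5
#' @export
signed_triangle_area <- function(l, m, p) {
  0.5 * ((m[1L] - l[1L]) * (p[2L] - l[2L]) - (m[2L] - l[2L]) * (p[1L] - l[1L]))
}

#' Extract a vertex matrix from a polygon-like object
#' @noRd
as_vertex_matrix <- function(p) {
  if (inherits(p, "convex_polygon")) return(p$vertices)
  v <- as.matrix(p)
  storage.mode(v) <- "double"
  if (ncol(v) != 2L) stop("polygon vertices must be an n x 2 matrix")
  v
}

#' Shoelace area of a polygon
#'
#' Signed area of the vertex loop; positive for CCW orientation. A negative
#' value for a deformed element signals inversion (the caller decides how to
#' react).
#'
#' @param v Polygon vertices (n x 2 matrix or `convex_polygon`).
#' @return Signed area in mm^2.
#' @export
polygon_area <- function(v) {
  v <- as_vertex_matrix(v)
  x <- v[, 1L]; y <- v[, 2L]
  xn <- c(x[-1L], x[1L]); yn <- c(y[-1L], y[1L])
  0.5 * sum(x * yn - xn * y)
}

#' Area centroid of a polygon
#' @param v Polygon vertices (n x 2 matrix or `convex_polygon`).
#' @return Length-2 centroid coordinates (mm).
#' @export
polygon_centroid <- function(v) {
  v <- as_vertex_matrix(v)
  x <- v[, 1L]; y <- v[, 2L]
  xn <- c(x[-1L], x[1L]); yn <- c(y[-1L], y[1L])
  cr <- x * yn - xn * y
  a <- 0.5 * sum(cr)
  if (abs(a) < .Machine$double.eps * max(1, sum(abs(v)))) return(colMeans(v))
  c(sum((x + xn) * cr), sum((y + yn) * cr)) / (6 * a)
}

#' Construct a validated convex polygon
#'
#' The element geometry everything else operates on: an ordered CCW vertex
#' loop with strictly positive area, convex up to a stated tolerance, and with
#' no two consecutive vertices closer than a snap distance.
#'
#' @param vertices n x 2 matrix of CCW vertex coordinates (mm), n >= 3.
#' @param eps_convex Convexity tolerance: every consecutive-edge cross product
#'   must be `>= -eps_convex * scale^2` where `scale` is the longest edge.
#' @param snap_tol Minimum allowed distance between consecutive vertices;
#'   defaults to `1e-9 * scale`.
#' @return An object of class `convex_polygon` with fields `vertices`, `n`,
#'   `area` and `scale`.
#' @export
convex_polygon <- function(vertices, eps_convex = 1e-9, snap_tol = NULL) {
  v <- as_vertex_matrix(vertices)
  n <- nrow(v)
  if (n < 3L) stop("a polygon needs at least 3 vertices")
  if (!all(is.finite(v))) stop("polygon vertices must be finite")
  ex <- c(v[-1L, 1L], v[1L, 1L]) - v[, 1L]
  ey <- c(v[-1L, 2L], v[1L, 2L]) - v[, 2L]
  len <- sqrt(ex^2 + ey^2)
  scale <- max(len)
  if (is.null(snap_tol)) snap_tol <- 1e-9 * scale
  if (any(len < snap_tol)) stop("repeated vertices closer than the snap distance")
  a <- polygon_area(v)
  if (a <= 0) stop("polygon must be CCW with strictly positive area")
  # cross product of consecutive edges
  exn <- c(ex[-1L], ex[1L]); eyn <- c(ey[-1L], ey[1L])
  crs <- ex * eyn - ey * exn
  if (any(crs < -eps_convex * scale^2)) stop("polygon is not convex")
  structure(list(vertices = v, n = n, area = a, scale = scale),
            class = "convex_polygon")
}

#' @export
print.convex_polygon <- function(x, ...) {
  cat(sprintf("<convex_polygon> n = %d, area = %.6g mm^2\n", x$n, x$area))
  invisible(x)
}

#' Even-odd point-in-polygon test
#'
#' @param pts k x 2 matrix (or length-2 vector) of query points.
#' @param poly Polygon vertices (matrix or `convex_polygon`). Works for any
#'   simple polygon, convex or not.
#' @return Logical vector of length k.
#' @export
point_in_polygon <- function(pts, poly) {
  if (is.null(dim(pts))) pts <- matrix(pts, ncol = 2L)
  v <- as_vertex_matrix(poly)
  n <- nrow(v)
  px <- pts[, 1L]; py <- pts[, 2L]
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- v[i, 1L]; yi <- v[i, 2L]
    xj <- v[j, 1L]; yj <- v[j, 2L]
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

#' Even-odd parity of points with respect to a set of closed loops
#' @param pts k x 2 matrix of query points.
#' @param loops List of loop vertex matrices.
#' @return Logical vector: TRUE where the point is enclosed by an odd number
#'   of loops.
#' @export
point_in_loops <- function(pts, loops) {
  if (is.null(dim(pts))) pts <- matrix(pts, ncol = 2L)
  inside <- rep(FALSE, nrow(pts))
  for (lp in loops) inside <- xor(inside, point_in_polygon(pts, lp))
  inside
}

# Douglas-Peucker simplification of an open polyline (first/last kept).
#' @noRd
dp_open <- function(pts, tol) {
  n <- nrow(pts)
  if (n <= 2L) return(pts)
  keep <- logical(n)
  keep[c(1L, n)] <- TRUE
  stack <- list(c(1L, n))
  while (length(stack)) {
    rng <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    i1 <- rng[1L]; i2 <- rng[2L]
    if (i2 - i1 < 2L) next
    a <- pts[i1, ]; b <- pts[i2, ]
    ab <- b - a
    len2 <- sum(ab^2)
    idx <- (i1 + 1L):(i2 - 1L)
    dx <- pts[idx, 1L] - a[1L]; dy <- pts[idx, 2L] - a[2L]
    if (len2 == 0) {
      d <- sqrt(dx^2 + dy^2)
    } else {
      d <- abs(dx * ab[2L] - dy * ab[1L]) / sqrt(len2)
    }
    k <- which.max(d)
    if (d[k] > tol) {
      m <- idx[k]
      keep[m] <- TRUE
      stack[[length(stack) + 1L]] <- c(i1, m)
      stack[[length(stack) + 1L]] <- c(m, i2)
    }
  }
  pts[keep, , drop = FALSE]
}

# Simplify a closed loop (matrix without repeated last vertex): anchor the
# first vertex and the vertex farthest from it, simplify the two arcs.
#' @noRd
simplify_loop <- function(pts, tol) {
  n <- nrow(pts)
  if (n <= 4L || tol <= 0) return(pts)
  d <- (pts[, 1L] - pts[1L, 1L])^2 + (pts[, 2L] - pts[1L, 2L])^2
  k <- which.max(d)
  if (k <= 2L) return(pts)
  arc1 <- dp_open(pts[1:k, , drop = FALSE], tol)
  arc2 <- dp_open(pts[c(k:n, 1L), , drop = FALSE], tol)
  out <- rbind(arc1, arc2[-c(1L, nrow(arc2)), , drop = FALSE])
  if (nrow(out) < 3L) pts else out
}

#' Merge nearly coincident points
#'
#' Clusters points closer than `tol` (via a quantized bucket grid with
#' neighbor lookup) and returns the merged coordinates plus an index map.
#' Used to make Voronoi and cut-cell meshes conforming.
#'
#' @param coords k x 2 matrix.
#' @param tol Merge distance (mm).
#' @return List with `coords` (m x 2 matrix of representatives, m <= k) and
#'   `map` (length-k integer vector into the merged rows).
#' @export
merge_points <- function(coords, tol) {
  k <- nrow(coords)
  map <- integer(k)
  reg <- new.env(hash = TRUE, parent = emptyenv())
  outx <- numeric(k); outy <- numeric(k)
  m <- 0L
  ix <- floor(coords[, 1L] / tol); iy <- floor(coords[, 2L] / tol)
  for (i in seq_len(k)) {
    found <- 0L
    for (dx in -1:1) {
      for (dy in -1:1) {
        key <- paste0(ix[i] + dx, "_", iy[i] + dy)
        ids <- reg[[key]]
        if (!is.null(ids)) {
          for (j in ids) {
            if ((coords[i, 1L] - outx[j])^2 + (coords[i, 2L] - outy[j])^2 <= tol^2) {
              found <- j; break
            }
          }
        }
        if (found) break
      }
      if (found) break
    }
    if (found) {
      map[i] <- found
    } else {
      m <- m + 1L
      outx[m] <- coords[i, 1L]; outy[m] <- coords[i, 2L]
      key <- paste0(ix[i], "_", iy[i])
      reg[[key]] <- c(reg[[key]], m)
      map[i] <- m
    }
  }
  list(coords = cbind(outx[seq_len(m)], outy[seq_len(m)]), map = map)
}
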