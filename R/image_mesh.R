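# Image -> polygonal mesh pipeline: uniform background squares inside each
# phase, boundary/interface cells split into convex polygon pairs along the
# straight chord between the two points where the interface crosses the cell
# boundary. Crossing points are computed once per global grid edge, so the
# two cells flanking an edge see bit-identical crossing nodes and the mesh is
# conforming by construction. Crossing points within `snap_frac * h` of a
# cell corner are merged onto that corner; nearly coincident crossings on one
# edge are merged with the same tolerance.

#' Uniform background grid
#' @param origin Lower-left corner (mm).
#' @param h Lattice length: grid spacing (mm), > 0.
#' @param nx,ny Number of cells in x and y.
#' @return Object of class `background_grid`.
#' @export
background_grid <- function(origin, h, nx, ny) {
  if (h <= 0) stop("lattice length h must be > 0")
  structure(list(origin = as.numeric(origin), h = as.numeric(h),
                 nx = as.integer(nx), ny = as.integer(ny)),
            class = "background_grid")
}

#' Background grid covering a label image
#' @param img A [label_image()].
#' @param h Lattice length (mm). Choose h dividing the image extent when the
#'   background phase is meshed too.
#' @return A [background_grid()].
#' @export
grid_for_image <- function(img, h) {
  ext <- image_extent(img)
  nx <- ceiling(ext$width / h - 1e-9)
  ny <- ceiling(ext$height / h - 1e-9)
  background_grid(img$origin, h, nx, ny)
}

# Transversal crossings of loop segments with the grid lines. Loop vertices
# closer than 1e-9 h to a grid line are nudged off it first, so collinear
# frame segments produce no crossings and near-line vertices produce exactly
# one. Returns a data.frame: orient ("V"/"H"), line (0-based grid line
# index), pos (coordinate along the line).
#' @noRd
crossings_on_grid <- function(grid, loops) {
  h <- grid$h; x0 <- grid$origin[1L]; y0 <- grid$origin[2L]
  tolg <- 1e-9 * h
  orient <- character(0L); line <- integer(0L); pos <- numeric(0L)
  for (lp in loops) {
    px <- lp[, 1L]; py <- lp[, 2L]
    # nudge vertices off grid lines
    fx <- (px - x0) / h
    on <- abs(fx - round(fx)) * h < tolg
    px[on] <- px[on] + 2 * tolg
    fy <- (py - y0) / h
    on <- abs(fy - round(fy)) * h < tolg
    py[on] <- py[on] + 2 * tolg
    qx <- c(px[-1L], px[1L]); qy <- c(py[-1L], py[1L])
    for (k in 0L:grid$nx) {
      xk <- x0 + k * h
      str <- (px - xk) * (qx - xk) < 0
      if (any(str)) {
        t <- (xk - px[str]) / (qx[str] - px[str])
        y <- py[str] + t * (qy[str] - py[str])
        keep <- y >= y0 - tolg & y <= y0 + grid$ny * h + tolg
        if (any(keep)) {
          orient <- c(orient, rep("V", sum(keep)))
          line <- c(line, rep(k, sum(keep)))
          pos <- c(pos, y[keep])
        }
      }
    }
    for (k in 0L:grid$ny) {
      yk <- y0 + k * h
      str <- (py - yk) * (qy - yk) < 0
      if (any(str)) {
        t <- (yk - py[str]) / (qy[str] - py[str])
        x <- px[str] + t * (qx[str] - px[str])
        keep <- x >= x0 - tolg & x <= x0 + grid$nx * h + tolg
        if (any(keep)) {
          orient <- c(orient, rep("H", sum(keep)))
          line <- c(line, rep(k, sum(keep)))
          pos <- c(pos, x[keep])
        }
      }
    }
  }
  data.frame(orient = orient, line = line, pos = pos,
             stringsAsFactors = FALSE)
}

# Snap crossings to corners, merge near-coincident crossings per edge, assign
# node keys and physical coordinates. Returns a data.frame with one row per
# surviving crossing: orient, line, interval (0-based cell interval along the
# line), x, y, key.
#' @noRd
process_crossings <- function(grid, cr, snap_frac = 0.01) {
  if (!nrow(cr)) {
    return(data.frame(orient = character(0), line = integer(0),
                      interval = integer(0), x = numeric(0), y = numeric(0),
                      key = character(0), stringsAsFactors = FALSE))
  }
  h <- grid$h; x0 <- grid$origin[1L]; y0 <- grid$origin[2L]
  o0 <- ifelse(cr$orient == "V", y0, x0)
  frac <- (cr$pos - o0) / h
  interval <- pmin(pmax(floor(frac), 0), ifelse(cr$orient == "V", grid$ny, grid$nx) - 1L)
  snapped <- abs(frac - round(frac)) <= snap_frac
  pos <- ifelse(snapped, o0 + round(frac) * h, cr$pos)
  df <- data.frame(orient = cr$orient, line = cr$line,
                   interval = as.integer(interval), pos = pos,
                   snapped = snapped, stringsAsFactors = FALSE)
  # merge near-coincident crossings on the same edge
  ekey <- paste0(df$orient, ":", df$line, ":", df$interval)
  keep <- logical(nrow(df))
  for (ix in split(seq_len(nrow(df)), ekey)) {
    ord <- ix[order(df$pos[ix])]
    last <- -Inf
    for (i in ord) {
      if (df$pos[i] - last > snap_frac * h) {
        keep[i] <- TRUE
        last <- df$pos[i]
      }
    }
  }
  df <- df[keep, , drop = FALSE]
  isV <- df$orient == "V"
  x <- ifelse(isV, x0 + df$line * h, df$pos)
  y <- ifelse(isV, df$pos, y0 + df$line * h)
  ci <- round((x - x0) / h); cj <- round((y - y0) / h)
  key <- ifelse(df$snapped,
                paste0("C:", ci, ":", cj),
                paste0("X:", df$orient, ":", df$line, ":",
                       round((df$pos - ifelse(isV, y0, x0)) / h * 1e9)))
  data.frame(orient = df$orient, line = df$line, interval = df$interval,
             x = x, y = y, key = key, stringsAsFactors = FALSE)
}

#' Classify background cells against boundary loops
#'
#' A cell is `"cut"` when a loop crosses its closed boundary transversally;
#' otherwise it is `"inside"` or `"outside"` by the even-odd parity of its
#' center with respect to the loops.
#'
#' @param grid A [background_grid()].
#' @param loops List of closed CCW loop matrices (mm).
#' @param snap_frac Corner snap tolerance as a fraction of h (default 0.01).
#' @return Character matrix `nx x ny` with values inside/outside/cut.
#' @export
classify_cells <- function(grid, loops, snap_frac = 0.01) {
  pc <- process_crossings(grid, crossings_on_grid(grid, loops), snap_frac)
  out <- matrix("", grid$nx, grid$ny)
  cut <- matrix(FALSE, grid$nx, grid$ny)
  if (nrow(pc)) {
    for (r in seq_len(nrow(pc))) {
      if (pc$orient[r] == "V") {
        cy <- pc$interval[r] + 1L
        for (cx in c(pc$line[r], pc$line[r] + 1L)) {
          if (cx >= 1L && cx <= grid$nx) cut[cx, cy] <- TRUE
        }
      } else {
        cx <- pc$interval[r] + 1L
        for (cy in c(pc$line[r], pc$line[r] + 1L)) {
          if (cy >= 1L && cy <= grid$ny) cut[cx, cy] <- TRUE
        }
      }
    }
  }
  cex <- grid$origin[1L] + (seq_len(grid$nx) - 0.5) * grid$h
  cey <- grid$origin[2L] + (seq_len(grid$ny) - 0.5) * grid$h
  centers <- cbind(rep(cex, times = grid$ny), rep(cey, each = grid$nx))
  ins <- point_in_loops(centers, loops)
  out[] <- ifelse(as.vector(cut), "cut",
                  ifelse(ins, "inside", "outside"))
  out
}

# Corners of square cell (cx, cy) in CCW order from the lower-left, and the
# boundary parameter s in [0, 4): s = 0..1 bottom, 1..2 right, 2..3 top,
# 3..4 left.
#' @noRd
cell_s_to_point <- function(grid, cx, cy, s) {
  h <- grid$h
  ox <- grid$origin[1L] + (cx - 1L) * h
  oy <- grid$origin[2L] + (cy - 1L) * h
  s <- s %% 4
  if (s < 1) c(ox + s * h, oy)
  else if (s < 2) c(ox + h, oy + (s - 1) * h)
  else if (s < 3) c(ox + (3 - s) * h, oy + h)
  else c(ox, oy + (4 - s) * h)
}

#' @noRd
cell_point_to_s <- function(grid, cx, cy, x, y) {
  h <- grid$h
  u <- (x - grid$origin[1L]) / h - (cx - 1L)
  v <- (y - grid$origin[2L]) / h - (cy - 1L)
  d <- c(v, 1 - u, 1 - v, u)  # distance to bottom/right/top/left edge lines
  e <- which.min(d)
  s <- switch(e, u, 1 + v, 3 - u, 4 - v)
  s %% 4
}

# Split the unit-parameter square boundary at chord endpoints s1, s2 (s in
# [0,4), integer s = corner). Returns the two CCW walks as s-vectors, each
# starting at one chord endpoint, passing the corners strictly between, and
# ending at the other endpoint.
#' @noRd
split_square_by_s <- function(s1, s2, tol = 1e-9) {
  walk <- function(sa, sb) {
    if (sb <= sa) sb <- sb + 4
    cs <- ceiling(sa + tol):floor(sb - tol)
    cs <- cs[cs > sa + tol & cs < sb - tol]
    c(sa, cs, sb) %% 4
  }
  list(A = walk(s1, s2), B = walk(s2, s1))
}

#' Case tag of a cut-cell polygon pair
#' @noRd
cut_case_tag <- function(n1, n2) {
  ns <- sort(c(n1, n2))
  if (ns[1L] == 3L && ns[2L] == 5L) "TRI_PENT"
  else if (ns[1L] == 3L && ns[2L] == 4L) "TRI_QUAD"
  else if (ns[1L] == 4L && ns[2L] == 4L) "QUAD_QUAD"
  else if (ns[1L] == 3L && ns[2L] == 3L) "TRI_TRI"
  else paste0("P", ns[1L], "_P", ns[2L])
}

#' Split one background cell by a boundary loop
#'
#' Finds the (exactly two, after snapping) transversal crossings of the loop
#' with the square cell boundary and splits the square along the straight
#' chord between them into two convex CCW polygons. Crossings within
#' `snap_frac * h` of a cell corner are merged onto the corner first. The two
#' areas sum to h^2; the four possible topologies are a triangle + pentagon,
#' triangle + quadrilateral, two quadrilaterals, and two triangles (chord
#' through two diagonally opposite corners).
#'
#' @param origin Lower-left corner of the cell (mm).
#' @param h Cell edge length (mm).
#' @param loop Closed CCW loop matrix (mm).
#' @param snap_frac Corner snap tolerance as a fraction of h (default 0.01).
#' @return List with `inside_polygon`, `outside_polygon`
#'   ([convex_polygon()]s; inside = enclosed by the loop) and `case_tag` in
#'   TRI_PENT, TRI_QUAD, QUAD_QUAD, TRI_TRI.
#' @export
split_cell <- function(origin, h, loop, snap_frac = 0.01) {
  grid <- background_grid(origin, h, 1L, 1L)
  pc <- process_crossings(grid, crossings_on_grid(grid, list(loop)), snap_frac)
  pc <- pc[!duplicated(pc$key), , drop = FALSE]
  if (nrow(pc) != 2L) {
    stop("ambiguous cut: cell at (", origin[1L], ", ", origin[2L], ") has ",
         nrow(pc), " boundary crossings; refine the background mesh (smaller h)")
  }
  s <- vapply(seq_len(2L), function(r) {
    cell_point_to_s(grid, 1L, 1L, pc$x[r], pc$y[r])
  }, numeric(1L))
  int_s <- abs(s - round(s)) < 1e-9
  if (!any(int_s) && floor(s[1L]) == floor(s[2L])) {
    stop("ambiguous cut: the loop enters and leaves the cell through the ",
         "same edge; refine the background mesh (smaller h)")
  }
  halves <- split_square_by_s(s[1L], s[2L])
  if (min(lengths(halves)) < 3L) {
    stop("degenerate cut: the chord collapses onto a cell edge after snapping")
  }
  polys <- lapply(halves, function(sv) {
    convex_polygon(t(vapply(sv, function(si) cell_s_to_point(grid, 1L, 1L, si),
                            numeric(2L))))
  })
  tag <- cut_case_tag(polys[[1L]]$n, polys[[2L]]$n)
  cen1 <- polygon_centroid(polys[[1L]])
  in1 <- point_in_polygon(cen1, loop)
  list(inside_polygon = if (in1) polys[[1L]] else polys[[2L]],
       outside_polygon = if (in1) polys[[2L]] else polys[[1L]],
       case_tag = tag)
}

#' Build a conforming polygonal mesh from a label image
#'
#' Extracts the sub-pixel interface loops of every phase after the first
#' (the first label in `phase_labels` is the background/matrix phase),
#' overlays a uniform background grid of spacing `h`, keeps full squares for
#' cells away from the interfaces, and splits every cut cell into its two
#' polygons, labeled by the phase containing their centroid. Elements whose
#' phase is not in `phase_labels` are dropped, so a single-phase call meshes
#' just that region.
#'
#' @param img A [label_image()].
#' @param h Lattice length (mm); `h >= 2 * pixel_size` recommended.
#' @param phase_labels Integer labels of the phases partitioning the image;
#'   the first is treated as the background phase (no loops of its own).
#' @param keep Labels of the phases to keep in the mesh (default all of
#'   `phase_labels`); e.g. keep only the organ phase of a segmented organ
#'   image to mesh just the organ.
#' @param snap_frac Corner snap tolerance as a fraction of h (default 0.01).
#' @param simplify_tol Loop simplification tolerance, see
#'   [extract_boundary_loops()].
#' @return A [poly_mesh()] with element regions named by label.
#' @export
build_mesh_from_image <- function(img, h, phase_labels, keep = phase_labels,
                                  snap_frac = 0.01, simplify_tol = NULL) {
  phase_labels <- as.integer(phase_labels)
  grid <- grid_for_image(img, h)
  fg <- phase_labels[-1L]
  loops_by_label <- lapply(fg, function(l) {
    extract_boundary_loops(img, l, simplify_tol)
  })
  names(loops_by_label) <- as.character(fg)
  all_loops <- do.call(c, c(loops_by_label, list(list())))
  pc <- process_crossings(grid, crossings_on_grid(grid, all_loops), snap_frac)

  # per-edge lookup of crossing rows
  elook <- new.env(hash = TRUE, parent = emptyenv())
  if (nrow(pc)) {
    ek <- paste0(pc$orient, ":", pc$line, ":", pc$interval)
    for (ix in split(seq_len(nrow(pc)), ek)) elook[[ek[ix[1L]]]] <- ix
  }

  label_at <- function(pt) {
    for (l in rev(fg)) {
      if (point_in_loops(pt, loops_by_label[[as.character(l)]])) return(l)
    }
    phase_labels[1L]
  }

  nodes_env <- new.env(hash = TRUE, parent = emptyenv())
  coords <- list()
  node_id <- function(key, xy) {
    id <- nodes_env[[key]]
    if (is.null(id)) {
      id <- length(coords) + 1L
      coords[[id]] <<- xy
      nodes_env[[key]] <- id
    }
    id
  }
  corner_id <- function(ci, cj) {
    node_id(paste0("C:", ci, ":", cj),
            grid$origin + c(ci, cj) * h)
  }

  elements <- list(); regions <- character(0L)
  add_element <- function(ids, label) {
    elements[[length(elements) + 1L]] <<- ids
    regions[length(regions) + 1L] <<- as.character(label)
  }

  for (cy in seq_len(grid$ny)) {
    for (cx in seq_len(grid$nx)) {
      rows <- integer(0L)
      edge_keys <- c(paste0("H:", cy - 1L, ":", cx - 1L),
                     paste0("V:", cx, ":", cy - 1L),
                     paste0("H:", cy, ":", cx - 1L),
                     paste0("V:", cx - 1L, ":", cy - 1L))
      for (k in edge_keys) {
        ix <- elook[[k]]
        if (!is.null(ix)) rows <- c(rows, ix)
      }
      rows <- rows[!duplicated(pc$key[rows])]
      cen <- grid$origin + c(cx - 0.5, cy - 0.5) * h
      ncr <- length(rows)
      degenerate <- FALSE
      if (ncr == 2L) {
        s <- vapply(rows, function(r) {
          cell_point_to_s(grid, cx, cy, pc$x[r], pc$y[r])
        }, numeric(1L))
        int_s <- abs(s - round(s)) < 1e-9
        if (floor(s[1L]) == floor(s[2L]) && !any(int_s)) {
          stop("ambiguous cut: loop enters and leaves cell (", cx, ", ", cy,
               ") through the same edge; refine the background mesh (smaller h)")
        }
        halves <- split_square_by_s(s[1L], s[2L])
        # a walk with fewer than 3 vertices means the chord collapsed onto a
        # cell edge (snapped corners / grazing contact): not a real cut
        if (min(lengths(halves)) < 3L) degenerate <- TRUE
      }
      if (ncr <= 1L || (ncr == 2L && degenerate)) {
        lab <- label_at(cen)
        if (lab %in% keep) {
          ids <- c(corner_id(cx - 1L, cy - 1L), corner_id(cx, cy - 1L),
                   corner_id(cx, cy), corner_id(cx - 1L, cy))
          add_element(ids, lab)
        }
      } else if (ncr == 2L) {
        for (sv in halves) {
          ids <- integer(length(sv))
          vxy <- matrix(0, length(sv), 2L)
          for (q in seq_along(sv)) {
            si <- sv[q]
            if (abs(si - round(si)) < 1e-9) {
              corner <- round(si) %% 4
              ci <- cx - 1L + (corner %in% c(1, 2))
              cj <- cy - 1L + (corner %in% c(2, 3))
              ids[q] <- corner_id(ci, cj)
              vxy[q, ] <- grid$origin + c(ci, cj) * h
            } else {
              r <- if (abs(si - s[1L]) < 1e-9) rows[1L] else rows[2L]
              ids[q] <- node_id(pc$key[r], c(pc$x[r], pc$y[r]))
              vxy[q, ] <- c(pc$x[r], pc$y[r])
            }
          }
          lab <- label_at(polygon_centroid(vxy))
          if (lab %in% keep) add_element(ids, lab)
        }
      } else {
        stop("ambiguous cut: cell (", cx, ", ", cy, ") has ", ncr,
             " boundary crossings; refine the background mesh (smaller h)")
      }
    }
  }
  if (!length(elements)) stop("no elements: none of the requested phases cover the grid")
  nd <- do.call(rbind, coords)
  # drop unused nodes (all registered nodes are used by construction)
  poly_mesh(nd, elements, regions)
}

#' Census of cut-cell topologies under a deterministic chord sweep
#'
#' Sweeps straight chords over the unit square on a deterministic grid of
#' `n_angles` directions times `n_offsets` signed offsets from the square
#' center, applies the corner snap, splits each admissible chord with the
#' same boundary-walk splitter the mesher uses, and tallies the polygon-pair
#' topologies. Degenerate chords (tangent, corner-grazing, or collapsing to a
#' cell edge after snapping) are skipped.
#'
#' @param n_angles,n_offsets Sweep resolution (default 100 x 100).
#' @param snap_frac Corner snap tolerance (default 0.01 of the edge length).
#' @return Named integer vector of counts per case tag.
#' @export
cut_case_census <- function(n_angles = 100L, n_offsets = 100L,
                            snap_frac = 0.01) {
  tally <- integer(0L)
  point_to_s_unit <- function(p) {
    d <- c(p[2L], 1 - p[1L], 1 - p[2L], p[1L])
    e <- which.min(d)
    s <- switch(e, p[1L], 1 + p[2L], 3 - p[1L], 4 - p[2L])
    s %% 4
  }
  for (i in seq_len(n_angles)) {
    th <- (i - 1) / n_angles * pi
    dvec <- c(cos(th), sin(th))
    nvec <- c(-sin(th), cos(th))
    w <- abs(nvec[1L]) + abs(nvec[2L])   # projection width of the square
    for (j in seq_len(n_offsets)) {
      cc <- (j - n_offsets / 2) / (n_offsets - 1) * w / 2
      p0 <- c(0.5, 0.5) + cc * nvec
      # Liang-Barsky slab clip of the infinite line against [0,1]^2
      tmin <- -Inf; tmax <- Inf; ok <- TRUE
      for (ax in 1:2) {
        if (abs(dvec[ax]) < 1e-14) {
          if (p0[ax] < 0 || p0[ax] > 1) { ok <- FALSE; break }
        } else {
          t1 <- (0 - p0[ax]) / dvec[ax]; t2 <- (1 - p0[ax]) / dvec[ax]
          tmin <- max(tmin, min(t1, t2)); tmax <- min(tmax, max(t1, t2))
        }
      }
      if (!ok || tmax - tmin < 1e-12) next
      p1 <- p0 + tmin * dvec; p2 <- p0 + tmax * dvec
      s1 <- point_to_s_unit(p1); s2 <- point_to_s_unit(p2)
      if (abs(s1 - round(s1)) <= snap_frac) s1 <- round(s1) %% 4
      if (abs(s2 - round(s2)) <= snap_frac) s2 <- round(s2) %% 4
      if (abs(s1 - s2) < 1e-12) next
      ints <- abs(c(s1, s2) - round(c(s1, s2))) < 1e-9
      if (all(ints)) {
        ds <- abs(round(s1) - round(s2)) %% 4
        if (ds == 1 || ds == 3 || ds == 0) next   # chord degenerates to an edge
      } else if (!any(ints) && floor(s1) == floor(s2)) {
        next                                       # both endpoints on one edge
      }
      halves <- split_square_by_s(s1, s2)
      if (min(lengths(halves)) < 3L) next
      tag <- cut_case_tag(length(halves$A), length(halves$B))
      tally[tag] <- if (is.na(tally[tag])) 1L else tally[tag] + 1L
    }
  }
  tally[order(names(tally))]
}
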