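# Mesh / result export and configuration parsing: legacy-VTK unstructured
# grids with polygon cells, a plain JSON mesh dialect, materials and
# boundary-condition JSON.

#' Write a mesh as a legacy VTK unstructured grid
#'
#' Polygon cells (VTK cell type 7), z = 0. Optional nodal vector/scalar
#' fields and per-cell scalar fields.
#'
#' @param mesh A [poly_mesh()].
#' @param path Output file.
#' @param point_data Named list of nodal fields (N-vector or N x 2 matrix).
#' @param cell_data Named list of per-element scalar vectors.
#' @export
write_mesh_vtk <- function(mesh, path, point_data = list(), cell_data = list()) {
  con <- file(path, "w")
  on.exit(close(con))
  N <- nrow(mesh$nodes)
  ne <- length(mesh$elements)
  writeLines(c("# vtk DataFile Version 3.0",
               "polylat polygonal lattice mesh",
               "ASCII",
               "DATASET UNSTRUCTURED_GRID",
               sprintf("POINTS %d double", N)), con)
  writeLines(sprintf("%.10g %.10g 0", mesh$nodes[, 1L], mesh$nodes[, 2L]), con)
  sizes <- lengths(mesh$elements)
  writeLines(sprintf("CELLS %d %d", ne, sum(sizes) + ne), con)
  writeLines(vapply(mesh$elements, function(el) {
    paste(c(length(el), el - 1L), collapse = " ")
  }, character(1L)), con)
  writeLines(sprintf("CELL_TYPES %d", ne), con)
  writeLines(rep("7", ne), con)
  if (length(point_data)) {
    writeLines(sprintf("POINT_DATA %d", N), con)
    for (nm in names(point_data)) {
      v <- point_data[[nm]]
      if (is.matrix(v)) {
        writeLines(sprintf("VECTORS %s double", nm), con)
        writeLines(sprintf("%.10g %.10g 0", v[, 1L], v[, 2L]), con)
      } else {
        writeLines(c(sprintf("SCALARS %s double 1", nm),
                     "LOOKUP_TABLE default"), con)
        writeLines(sprintf("%.10g", v), con)
      }
    }
  }
  if (length(cell_data)) {
    writeLines(sprintf("CELL_DATA %d", ne), con)
    for (nm in names(cell_data)) {
      writeLines(c(sprintf("SCALARS %s double 1", nm),
                   "LOOKUP_TABLE default"), con)
      writeLines(sprintf("%.10g", cell_data[[nm]]), con)
    }
  }
  invisible(path)
}

#' Write a mesh as plain JSON
#'
#' Dialect: `{"nodes": [[x, y], ...], "elements": [[i, j, k, ...], ...],
#' "labels": [...]}` with 1-based node indices.
#'
#' @param mesh A [poly_mesh()].
#' @param path Output file.
#' @export
write_mesh_json <- function(mesh, path) {
  obj <- list(nodes = unname(apply(mesh$nodes, 1L, as.numeric, simplify = FALSE)),
              elements = lapply(mesh$elements, as.integer),
              labels = mesh$regions)
  jsonlite::write_json(obj, path, auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' Read a mesh from the plain JSON dialect
#' @param path JSON file written by [write_mesh_json()].
#' @return A [poly_mesh()].
#' @export
read_mesh_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyMatrix = TRUE)
  nodes <- if (is.list(obj$nodes)) do.call(rbind, obj$nodes) else obj$nodes
  elements <- if (is.list(obj$elements)) obj$elements else
    apply(obj$elements, 1L, identity, simplify = FALSE)
  poly_mesh(nodes, elements, obj$labels)
}

#' Read a materials map from JSON
#'
#' Format: `{"<region_label>": {"mu_kPa": .., "K_kPa": ..}, ...}`.
#'
#' @param path JSON file.
#' @return Named list of [material()].
#' @export
read_materials_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  lapply(obj, function(m) material(m$mu_kPa, m$K_kPa))
}

#' Parse boundary conditions from JSON
#'
#' An array of objects, each either a Dirichlet condition
#' `{"where": "y==max", "u": [0, 10.0]}` (use `null` for a free component)
#' or a traction `{"where": "x==max", "traction_kPa": [0, 1.0]}`.
#'
#' @param path JSON file.
#' @return List of boundary-condition objects.
#' @export
read_bcs_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  lapply(obj, function(b) {
    if (!is.null(b$u)) {
      u <- vapply(b$u, function(z) if (is.null(z)) NA_real_ else as.numeric(z),
                  numeric(1L))
      bc_dirichlet(b$where, u)
    } else if (!is.null(b$traction_kPa)) {
      bc_traction(b$where, as.numeric(unlist(b$traction_kPa)))
    } else {
      stop("boundary condition needs 'u' or 'traction_kPa'")
    }
  })
}
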