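# Polygonal mesh container and queries. A poly_mesh stores reference node
# coordinates, elements as CCW node-index loops, and a material region label
# per element; meshes are conforming (elements sharing a geometric edge share
# node indices).

#' Construct a polygonal mesh
#'
#' @param nodes N x 2 matrix of reference node coordinates (mm).
#' @param elements List of integer vectors, each a CCW loop of node indices.
#' @param regions Material region label per element (recycled if length 1).
#' @param validate Check index ranges and positive element areas.
#' @return Object of class `poly_mesh`.
#' @export
poly_mesh <- function(nodes, elements, regions = "domain", validate = TRUE) {
  nodes <- as.matrix(nodes)
  storage.mode(nodes) <- "double"
  if (ncol(nodes) != 2L) stop("nodes must be an N x 2 matrix")
  elements <- lapply(elements, as.integer)
  regions <- rep_len(as.character(regions), length(elements))
  if (validate) {
    N <- nrow(nodes)
    for (e in seq_along(elements)) {
      el <- elements[[e]]
      if (length(el) < 3L) stop("element ", e, " has fewer than 3 nodes")
      if (any(el < 1L | el > N)) stop("element ", e, " has out-of-range node index")
      if (polygon_area(nodes[el, , drop = FALSE]) <= 0) {
        stop("element ", e, " has non-positive area (must be CCW)")
      }
    }
  }
  structure(list(nodes = nodes, elements = elements, regions = regions),
            class = "poly_mesh")
}

#' @export
print.poly_mesh <- function(x, ...) {
  ns <- lengths(x$elements)
  cat(sprintf("<poly_mesh> %d nodes, %d elements (n = %d..%d), regions: %s\n",
              nrow(x$nodes), length(x$elements), min(ns), max(ns),
              paste(unique(x$regions), collapse = ", ")))
  invisible(x)
}

#' Vertex coordinates of one element
#' @param mesh A [poly_mesh()].
#' @param e Element index.
#' @return n x 2 matrix.
#' @export
mesh_element_vertices <- function(mesh, e) {
  mesh$nodes[mesh$elements[[e]], , drop = FALSE]
}

#' Reference areas of all elements
#' @param mesh A [poly_mesh()].
#' @return Numeric vector (mm^2).
#' @export
mesh_areas <- function(mesh) {
  vapply(mesh$elements, function(el) {
    polygon_area(mesh$nodes[el, , drop = FALSE])
  }, numeric(1L))
}

#' Element centroids
#' @param mesh A [poly_mesh()].
#' @return n_elements x 2 matrix.
#' @export
element_centroids <- function(mesh) {
  t(vapply(mesh$elements, function(el) {
    polygon_centroid(mesh$nodes[el, , drop = FALSE])
  }, numeric(2L)))
}

# Undirected edge table: one row per directed element edge with a sortable key.
#' @noRd
mesh_edge_table <- function(mesh) {
  a <- unlist(lapply(mesh$elements, function(el) el))
  b <- unlist(lapply(mesh$elements, function(el) c(el[-1L], el[1L])))
  elem <- rep(seq_along(mesh$elements), lengths(mesh$elements))
  key <- paste0(pmin(a, b), "_", pmax(a, b))
  data.frame(a = a, b = b, elem = elem, key = key, stringsAsFactors = FALSE)
}

#' Boundary edges of a mesh
#'
#' Edges that belong to exactly one element, returned with the orientation
#' they have in that element (domain on the left).
#'
#' @param mesh A [poly_mesh()].
#' @return data.frame with columns `a`, `b` (node indices) and `elem`.
#' @export
boundary_edges <- function(mesh) {
  et <- mesh_edge_table(mesh)
  cnt <- table(et$key)
  et[cnt[et$key] == 1L, c("a", "b", "elem")]
}

#' Nodes on the mesh boundary
#' @param mesh A [poly_mesh()].
#' @return Integer vector of node indices.
#' @export
boundary_nodes <- function(mesh) {
  be <- boundary_edges(mesh)
  sort(unique(c(be$a, be$b)))
}

#' Check mesh conformity
#'
#' A conforming polygonal mesh has every interior edge shared by exactly two
#' elements (with opposite orientation) and no edge shared by more than two.
#'
#' @param mesh A [poly_mesh()].
#' @return TRUE/FALSE, with attribute `max_edge_multiplicity`.
#' @export
mesh_is_conforming <- function(mesh) {
  et <- mesh_edge_table(mesh)
  cnt <- table(et$key)
  ok <- all(cnt <= 2L)
  if (ok) {
    # interior edges must appear once in each direction
    dup <- et$key[duplicated(et$key)]
    if (length(dup)) {
      dkey <- paste0(et$a, "_", et$b)
      ok <- !any(duplicated(dkey[et$key %in% dup]))
    }
  }
  structure(ok, max_edge_multiplicity = max(cnt))
}

#' Connected groups of same-region elements
#'
#' Counts connected components of the elements carrying a given region label,
#' where two elements are adjacent when they share a full geometric edge.
#'
#' @param mesh A [poly_mesh()].
#' @param label Region label.
#' @return Number of connected components (integer).
#' @export
mesh_region_components <- function(mesh, label) {
  sel <- which(mesh$regions == as.character(label))
  if (!length(sel)) return(0L)
  et <- mesh_edge_table(mesh)
  et <- et[et$elem %in% sel, ]
  # union-find over selected elements linked by shared edges
  parent <- seq_along(sel)
  pos <- integer(length(mesh$elements)); pos[sel] <- seq_along(sel)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  sp <- split(et$elem, et$key)
  for (p in sp) {
    if (length(p) == 2L) {
      r1 <- find(pos[p[1L]]); r2 <- find(pos[p[2L]])
      if (r1 != r2) parent[r1] <- r2
    }
  }
  length(unique(vapply(seq_along(sel), find, integer(1L))))
}
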