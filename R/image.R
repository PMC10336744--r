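# Segmented label images and sub-pixel boundary extraction. Physical
# convention: mm coordinates, y-axis up, the corner of pixel (1,1) at the
# image origin (default (0,0)); pixel centers sit at (i - 1/2, j - 1/2) times
# the pixel size. labels[i, j] indexes x first, y (upwards) second.

#' Construct a label image
#'
#' @param labels Integer matrix of phase labels, indexed `[x, y]` with y up.
#' @param pixel_size Physical pixel edge length (mm/pixel), > 0.
#' @param origin Physical coordinates (mm) of the lower-left image corner.
#' @return Object of class `label_image`.
#' @export
label_image <- function(labels, pixel_size, origin = c(0, 0)) {
  labels <- as.matrix(labels)
  storage.mode(labels) <- "integer"
  if (!is.finite(pixel_size) || pixel_size <= 0) stop("pixel_size must be > 0")
  structure(list(labels = labels, pixel_size = as.numeric(pixel_size),
                 origin = as.numeric(origin)),
            class = "label_image")
}

#' @export
print.label_image <- function(x, ...) {
  cat(sprintf("<label_image> %d x %d px at %g mm/px, labels: %s\n",
              nrow(x$labels), ncol(x$labels), x$pixel_size,
              paste(sort(unique(as.vector(x$labels))), collapse = ", ")))
  invisible(x)
}

#' Physical extent of a label image
#' @param img A [label_image()].
#' @return Named list with `width`, `height` (mm).
#' @export
image_extent <- function(img) {
  list(width = nrow(img$labels) * img$pixel_size,
       height = ncol(img$labels) * img$pixel_size)
}

#' Read a label image from an 8-bit PNG
#'
#' Gray (or first-channel) pixel values times 255, rounded, are the integer
#' labels. The PNG row order (top to bottom) is flipped into the package's
#' y-up convention.
#'
#' @param path PNG file path.
#' @param pixel_size mm per pixel.
#' @param origin Lower-left corner (mm).
#' @return A [label_image()].
#' @export
read_label_png <- function(path, pixel_size, origin = c(0, 0)) {
  arr <- png::readPNG(path)
  if (length(dim(arr)) == 3L) arr <- arr[, , 1L]
  m <- round(arr * 255)
  label_image(t(m[nrow(m):1L, , drop = FALSE]), pixel_size, origin)
}

#' Write a label image to an 8-bit gray PNG
#' @param img A [label_image()].
#' @param path Output path.
#' @export
write_label_png <- function(img, path) {
  m <- t(img$labels)
  m <- m[ncol(img$labels):1L, , drop = FALSE]
  png::writePNG(m / 255, path)
  invisible(path)
}

#' Extract sub-pixel boundary loops of a labeled phase
#'
#' Marching-squares contours of the phase indicator at the 0.5 iso-level
#' (via [grDevices::contourLines()] on the zero-padded indicator), followed
#' by Douglas-Peucker simplification with tolerance `0.25 * pixel_size`.
#' Contours touching the image frame close along the frame because of the
#' padding. One loop is returned per connected region of the label; all loops
#' are closed, simple, and oriented CCW. An absent label yields an empty
#' list.
#'
#' @param img A [label_image()].
#' @param label The phase label whose boundary is wanted.
#' @param simplify_tol Douglas-Peucker tolerance (mm); default
#'   `0.25 * pixel_size`.
#' @return List of loop vertex matrices (mm, CCW, no repeated last vertex).
#' @export
extract_boundary_loops <- function(img, label, simplify_tol = NULL) {
  ps <- img$pixel_size
  if (is.null(simplify_tol)) simplify_tol <- 0.25 * ps
  nx <- nrow(img$labels); ny <- ncol(img$labels)
  Z <- matrix(0, nx + 2L, ny + 2L)
  Z[2L:(nx + 1L), 2L:(ny + 1L)] <- (img$labels == label) * 1
  if (all(Z == 0)) return(list())
  xc <- img$origin[1L] + ((0L:(nx + 1L)) - 0.5) * ps
  yc <- img$origin[2L] + ((0L:(ny + 1L)) - 0.5) * ps
  cls <- grDevices::contourLines(xc, yc, Z, levels = 0.5)
  loops <- list()
  for (cl in cls) {
    pts <- cbind(cl$x, cl$y)
    if (nrow(pts) > 1L && all(pts[1L, ] == pts[nrow(pts), ])) {
      pts <- pts[-nrow(pts), , drop = FALSE]
    }
    if (nrow(pts) < 3L) next
    pts <- simplify_loop(pts, simplify_tol)
    if (nrow(pts) < 3L) next
    if (polygon_area(pts) < 0) pts <- pts[nrow(pts):1L, , drop = FALSE]
    loops[[length(loops) + 1L]] <- pts
  }
  loops
}
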