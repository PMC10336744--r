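# Image -> mesh pipeline: boundary extraction, cell classification, cut-cell
# splitting, and full mesh construction.

test_that("boundary extraction finds frame, disc and disjoint-disc loops", {
  # uniform image: one loop along the frame (marching squares chamfers the
  # four right-angle corners by half a pixel)
  img1 <- label_image(matrix(1L, 10, 10), 0.5)
  l1 <- extract_boundary_loops(img1, 1L)
  expect_length(l1, 1L)
  expect_equal(apply(l1[[1]], 2, range), cbind(c(0, 5), c(0, 5)))
  expect_equal(polygon_area(l1[[1]]), 25, tolerance = 0.01)
  # rasterized disc: one loop, area within 2%
  img <- make_circle_inclusion_image(20, 10, c(10, 5), 2.5, 10)
  loops <- extract_boundary_loops(img, 1L)
  expect_length(loops, 1L)
  expect_equal(polygon_area(loops[[1]]), pi * 2.5^2, tolerance = 0.02)
  # two disjoint discs: two loops; absent label: none
  img2 <- make_composite_image(30, 30, 4, rbind(c(9, 9), c(21, 21)), 10)
  expect_length(extract_boundary_loops(img2, 1L), 2L)
  expect_length(extract_boundary_loops(img2, 7L), 0L)
})

test_that("cell classification sandwiches the disc area between inside and inside+cut", {
  img <- make_circle_inclusion_image(20, 10, c(10, 5), 2.5, 10)
  loops <- extract_boundary_loops(img, 1L)
  grid <- grid_for_image(img, 1)
  cls <- classify_cells(grid, loops)
  ninside <- sum(cls == "inside")
  ncut <- sum(cls == "cut")
  disc <- pi * 2.5^2
  expect_lte(ninside, disc)
  expect_gte(ninside + ncut, disc)
  # a loop containing the whole grid: everything inside
  big <- rbind(c(-5, -5), c(25, -5), c(25, 15), c(-5, 15))
  expect_true(all(classify_cells(grid, list(big)) == "inside"))
})

test_that("split_cell produces the four chord topologies with conserved area", {
  # chord across two opposite edges -> two quadrilaterals
  lq <- rbind(c(-1, -1), c(3, -1), c(3, 0.55), c(-1, 0.55))
  r <- split_cell(c(0, 0), 1, lq)
  expect_equal(r$case_tag, "QUAD_QUAD")
  expect_equal(r$inside_polygon$area + r$outside_polygon$area, 1,
               tolerance = 1e-10)
  expect_equal(r$inside_polygon$area, 0.55, tolerance = 1e-9)
  # chord across two adjacent edges -> triangle + pentagon
  lt <- rbind(c(1.4, -1), c(-1, 1.4), c(-1, -1))
  r2 <- split_cell(c(0, 0), 1, lt)
  expect_equal(r2$case_tag, "TRI_PENT")
  expect_equal(r2$inside_polygon$n, 3L)
  expect_equal(r2$inside_polygon$area + r2$outside_polygon$area, 1,
               tolerance = 1e-10)
  # chord through a snapped corner -> triangle + quadrilateral: the segment
  # crosses the bottom edge at x = 0.005 (snapped to the corner) and the top
  # edge at x = 0.7
  l3 <- rbind(c(-0.3425, -0.5), c(1.0475, 1.5), c(-2, 1.5))
  r3 <- split_cell(c(0, 0), 1, l3)
  expect_equal(sort(c(r3$inside_polygon$n, r3$outside_polygon$n)), c(3L, 4L))
  expect_equal(r3$case_tag, "TRI_QUAD")
  # chord through two diagonally opposite corners (after snap) -> two triangles
  ld <- rbind(c(-1, -1.004), c(3, 2.996), c(-1, 3))
  r4 <- split_cell(c(0, 0), 1, ld)
  expect_equal(r4$case_tag, "TRI_TRI")
  # a loop wiggling in and out through one edge is ambiguous
  lw <- rbind(c(0.2, -1), c(0.3, 0.5), c(0.4, -1), c(0.2, -1.5))
  expect_error(split_cell(c(0, 0), 1, lw), "ambiguous|same edge")
})

test_that("meshing a disc image conserves labeled area within the perimeter band", {
  img <- make_circle_inclusion_image(20, 10, c(10, 5), 2.5, 10)
  h <- 1
  mesh <- build_mesh_from_image(img, h, c(0L, 1L))
  expect_true(mesh_is_conforming(mesh))
  areas <- mesh_areas(mesh)
  expect_equal(sum(areas), 200, tolerance = 1e-9)
  inc <- sum(areas[mesh$regions == "1"])
  expect_lt(abs(inc - pi * 2.5^2), 1.5 * h * (2 * pi * 2.5))
  # interior of a homogeneous region keeps exact h x h squares
  ns <- lengths(mesh$elements)
  sq <- which(ns == 4L)
  sq_areas <- areas[sq]
  full <- abs(sq_areas - h^2) < 1e-9
  expect_gt(sum(full), 0.8 * length(sq))
  # determinism
  mesh2 <- build_mesh_from_image(img, h, c(0L, 1L))
  expect_identical(mesh$nodes, mesh2$nodes)
  expect_identical(mesh$elements, mesh2$elements)
})

test_that("cut-cell polygon pairs sum to h^2 across a whole cut mesh", {
  img <- make_circle_inclusion_image(20, 10, c(10, 5), 2.5, 10)
  h <- 1
  mesh <- build_mesh_from_image(img, h, c(0L, 1L))
  # group non-square elements by the grid cell containing their centroid
  cen <- element_centroids(mesh)
  ns <- lengths(mesh$elements)
  cut <- which(ns != 4L | abs(mesh_areas(mesh) - h^2) > 1e-9)
  cell <- paste(floor(cen[cut, 1] / h), floor(cen[cut, 2] / h))
  sums <- tapply(mesh_areas(mesh)[cut], cell, sum)
  expect_true(all(abs(sums - h^2) < 1e-9 * h^2))
})

test_that("the bilayer mesh reproduces the analytic lower-phase area", {
  img <- make_bilayer_image()  # 20 x 10 mm, amplitude 2, one period
  mesh <- build_mesh_from_image(img, 1, c(0L, 1L))
  expect_true(mesh_is_conforming(mesh))
  lower <- sum(mesh_areas(mesh)[mesh$regions == "0"])
  # integral of (5 + 2 sin(2 pi x / 20)) over [0, 20] = 100
  expect_equal(lower, 100, tolerance = 0.02)
})
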