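# Boundary conditions, load lumping, and the static solver.

test_that("edge-load lumping is trapezoidal and refinement-invariant", {
  # one boundary edge of length 2 under unit vertical traction
  mesh <- grid_mesh(1, 1, h = 2)
  FF <- consistent_edge_loads(mesh, bc_traction("y==min", c(0, 1)))
  bot <- which(mesh$nodes[, 2] == 0)
  expect_equal(FF[bot, 2], rep(1, 2))
  expect_equal(colSums(FF), c(0, 2))
  # splitting the edge in two leaves the total unchanged
  mesh2 <- grid_mesh(2, 1, h = 1)
  FF2 <- consistent_edge_loads(mesh2, bc_traction("y==min", c(0, 1)))
  expect_equal(colSums(FF2), c(0, 2))
  # Cook membrane right edge: total vertical load = 16 kPa mm
  cook <- cvt_polygonal_mesh(cook_domain(), 60, iterations = 25, seed = 11)
  Fc <- consistent_edge_loads(cook, bc_traction("x==max", c(0, 1)))
  expect_equal(colSums(Fc), c(0, 16), tolerance = 1e-9)
  expect_error(consistent_edge_loads(mesh, bc_traction("y==7", c(0, 1))),
               "matched no")
})

test_that("zero loading returns the reference state", {
  mesh <- grid_mesh(4, 4)
  sol <- solve_static(mesh, list(domain = material(1, 100)),
                      list(bc_dirichlet("y==min", c(0, 0))),
                      solve_config(steps = 2))
  expect_true(sol$converged)
  expect_lt(max(abs(sol$u)), 1e-9)
  expect_equal(max(abs(sol$J - 1)), 0, tolerance = 1e-9)
})

test_that("a rigid translation prescribed on the whole boundary is followed exactly", {
  mesh <- grid_mesh(5, 4)
  bn <- boundary_nodes(mesh)
  sol <- solve_static(mesh, list(domain = material(1, 100)),
                      list(bc_dirichlet(function(nd) {
                        seq_len(nrow(nd)) %in% bn
                      }, c(3, -2))),
                      solve_config(steps = 4))
  expect_true(sol$converged)
  expect_lt(max(abs(sweep(sol$u, 2, c(3, -2)))), 1e-7)
  expect_lt(sol$energy[length(sol$energy)], 1e-10)
})

test_that("uniaxial tension with lateral-free grips recovers the closed-form lateral stretch", {
  mesh <- cvt_polygonal_mesh(domain_rectangle(20, 10), 200, iterations = 50,
                             seed = 3)
  pin <- which.min(rowSums(mesh$nodes^2))
  bcs <- list(bc_dirichlet("y==min", c(NA, 0)),
              bc_dirichlet("y==max", c(NA, 10)),
              bc_dirichlet(function(nd) seq_len(nrow(nd)) == pin, c(0, NA)))
  sol <- solve_static(mesh, list(domain = material(1, 100)), bcs,
                      solve_config(steps = 10))
  expect_true(sol$converged)
  bn <- boundary_nodes(mesh)
  interior <- which(vapply(mesh$elements, function(el) !any(el %in% bn),
                           logical(1)))
  sys <- sol$system
  F11 <- vapply(interior, function(e) {
    op <- sys$ops[[e]]
    element_deformation_gradient(op, sol$x[op$node_indices, ])[1, 1]
  }, numeric(1))
  expect_equal(mean(F11), 202 / 401, tolerance = 0.005 / (202 / 401))
})

test_that("the clamped uniaxial benchmark stays nearly incompressible without locking", {
  mesh <- cvt_polygonal_mesh(domain_rectangle(20, 10), 200, iterations = 50,
                             seed = 3)
  bcs <- list(bc_dirichlet("y==min", c(0, 0)),
              bc_dirichlet("y==max", c(0, 10)))
  sol <- solve_static(mesh, list(domain = material(1, 100)), bcs,
                      solve_config(steps = 10))
  expect_true(sol$converged)
  bn <- boundary_nodes(mesh)
  interior <- which(vapply(mesh$elements, function(el) !any(el %in% bn),
                           logical(1)))
  expect_lte(max(abs(sol$J[interior] - 1)), 0.05)
  # sum of reactions vanishes without applied loads
  expect_lt(max(abs(colSums(sol$reactions))), 1e-8)
  # no volumetric locking signature: the displacement error against the
  # homogeneous roller solution does not grow by more than 2% in L2 as K/mu
  # rises from 10 to 100
  pin <- which.min(rowSums(mesh$nodes^2))
  roller <- list(bc_dirichlet("y==min", c(NA, 0)),
                 bc_dirichlet("y==max", c(NA, 10)),
                 bc_dirichlet(function(nd) seq_len(nrow(nd)) == pin, c(0, NA)))
  rel_err <- vapply(c(10, 100), function(K) {
    s <- solve_static(mesh, list(domain = material(1, K)), roller,
                      solve_config(steps = 10))
    l2 <- 2 * (1 + K) / (1 + 4 * K)
    xpin <- mesh$nodes[pin, 1]
    uex <- cbind(l2 * (mesh$nodes[, 1] - xpin) + xpin - mesh$nodes[, 1],
                 mesh$nodes[, 2])
    sqrt(mean(rowSums((s$u - uex)^2))) / sqrt(mean(rowSums(uex^2)))
  }, numeric(1))
  expect_lt(rel_err[2], rel_err[1] + 0.02)
})

test_that("Cook membrane reactions balance the applied traction", {
  mesh <- cvt_polygonal_mesh(cook_domain(), 150, iterations = 40, seed = 5)
  sol <- solve_static(mesh, list(domain = material(1, 100)),
                      list(bc_dirichlet("x==min", c(0, 0)),
                           bc_traction("x==max", c(0, 1))),
                      solve_config(steps = 5))
  expect_true(sol$converged)
  R <- colSums(sol$reactions)
  expect_lt(sqrt(sum((R + c(0, 16))^2)) / 16, 1e-6)
  # the sheared panel deflects upward
  expect_gt(max(sol$u[, 2]), 1)
})

test_that("a hard inclusion deforms less volumetrically than the matrix", {
  img <- make_circle_inclusion_image()
  mesh <- build_mesh_from_image(img, 1, c(0L, 1L))
  mats <- list(`0` = material(1, 100), `1` = material(10, 1000))
  sol <- solve_static(mesh, mats,
                      list(bc_dirichlet("y==min", c(0, 0)),
                           bc_dirichlet("y==max", c(0, 10))),
                      solve_config(steps = 10))
  expect_true(sol$converged)
  mJ <- tapply(abs(sol$J - 1), mesh$regions, mean)
  expect_lt(mJ[["1"]], mJ[["0"]])
})

test_that("interpolation reproduces nodal fields and linear functions", {
  mesh <- cvt_polygonal_mesh(domain_rectangle(10, 10), 40, iterations = 30,
                             seed = 13)
  lin <- cbind(2 * mesh$nodes[, 1] - mesh$nodes[, 2],
               0.5 * mesh$nodes[, 1] + 3)
  set.seed(1)
  pts <- cbind(runif(50, 0.2, 9.8), runif(50, 0.2, 9.8))
  vals <- interpolate_field(mesh, lin, pts)
  expect_equal(vals[, 1], 2 * pts[, 1] - pts[, 2], tolerance = 1e-9)
  expect_equal(vals[, 2], 0.5 * pts[, 1] + 3, tolerance = 1e-9)
})
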