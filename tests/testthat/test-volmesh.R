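# Tetrahedralization and the scaled-Jacobian quality audit.

test_that("knupp index matches its defining formula", {
  reg <- rbind(c(0, 0, 0), c(1, 0, 0), c(0.5, sqrt(3) / 2, 0),
               c(0.5, sqrt(3) / 6, sqrt(2 / 3)))
  expect_equal(knupp_index(reg), 1, tolerance = 1e-12)
  flat <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(1, 1, 0))
  expect_warning(q0 <- knupp_index(flat), "degenerate")
  expect_equal(q0, 0)
  # unit right-corner tet: direct evaluation of the corner formula
  corner <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  oracle <- min(vapply(1:4, function(v) {
    e <- corner[-v, , drop = FALSE] - matrix(corner[v, ], 3, 3, byrow = TRUE)
    sqrt(2) * abs(det(e)) / prod(sqrt(rowSums(e^2)))
  }, numeric(1)))
  expect_equal(knupp_index(corner), oracle, tolerance = 1e-12)
  expect_equal(knupp_index(corner), sqrt(2) / 2, tolerance = 1e-9)
})

test_that("knupp index is invariant to rigid motion and uniform scale", {
  set.seed(91)
  for (rep in 1:20) {
    tet <- matrix(rnorm(12, sd = 5), 4, 3)
    q0 <- suppressWarnings(knupp_index(tet))
    R <- cinemesh:::.axis_rotation(rnorm(3), runif(1, 0, 360))
    moved <- tet %*% t(R) * runif(1, 0.1, 10) + matrix(rnorm(3), 4, 3, byrow = TRUE)
    expect_equal(suppressWarnings(knupp_index(moved)), q0, tolerance = 1e-9)
  }
})

test_that("tetrahedralization fills cubes and spheres to the right volume", {
  V <- as.matrix(expand.grid(x = c(0, 10), y = c(0, 10), z = c(0, 10)))
  F <- rbind(c(1, 3, 2), c(2, 3, 4), c(5, 6, 7), c(6, 8, 7),
             c(1, 2, 5), c(2, 6, 5), c(3, 7, 4), c(4, 7, 8),
             c(1, 5, 3), c(3, 5, 7), c(2, 4, 6), c(4, 8, 6))
  cube <- surface_mesh(V, F)
  tm <- tetrahedralize(cube, target_edge = 0.7)
  expect_equal(sum(tet_volumes(tm$vertices, tm$tets)), 1000, tolerance = 0.01)
  expect_true(all(tet_volumes(tm$vertices, tm$tets) > 0))

  sp <- make_phantom_surfaces(phantom_spec_lv_only(c(10, 10, 10), base_height = Inf),
                              ring_spacing = 0.5, n_theta = 128)$lv_endo
  tms <- tetrahedralize(sp, target_edge = 1.0)
  expect_equal(sum(tet_volumes(tms$vertices, tms$tets)), 4 / 3 * pi * 1000,
               tolerance = 0.01)
  # boundary of the complex is watertight and close to the input sphere
  bs <- tet_boundary_surface(tms)
  expect_true(mesh_is_watertight(bs))
  expect_lt(max(abs(sqrt(rowSums(bs$vertices^2)) - 10)), 0.5)
  expect_error(tetrahedralize(surface_mesh(V[1:4, ], rbind(c(1, 2, 3))), 1),
               "watertight")
})

test_that("remeshing preserves area, stays close, and is stable", {
  sp <- make_phantom_surfaces(phantom_spec_lv_only(c(1, 1, 1) * 10, base_height = Inf),
                              ring_spacing = 0.4, n_theta = 160)$lv_endo
  # a sphere of radius 10 remeshed at 2 mm target edge
  rm <- remesh_surface(sp, target_edge = 2)
  expect_true(mesh_is_watertight(rm))
  expect_equal(mesh_area(rm), 4 * pi * 100, tolerance = 0.02)
  # median edge within the contract band
  e <- unique(cinemesh:::.mesh_edges(rm$triangles))
  el <- sqrt(rowSums((rm$vertices[e[, 1], ] - rm$vertices[e[, 2], ])^2))
  expect_gt(median(el), 0.6 * 2)
  expect_lt(median(el), 1.4 * 2)
  # Hausdorff to the input below half the target edge
  expect_lt(max(point_to_mesh_distance(rm$vertices, sp)), 1)
  # stability: remeshing the remesh moves the median edge by < 10%
  rm2 <- remesh_surface(rm, target_edge = 2)
  e2 <- unique(cinemesh:::.mesh_edges(rm2$triangles))
  el2 <- sqrt(rowSums((rm2$vertices[e2[, 1], ] - rm2$vertices[e2[, 2], ])^2))
  expect_lt(abs(median(el2) - median(el)) / median(el), 0.1)
})

test_that("quality summaries aggregate exactly", {
  reg <- rbind(c(0, 0, 0), c(1, 0, 0), c(0.5, sqrt(3) / 2, 0),
               c(0.5, sqrt(3) / 6, sqrt(2 / 3)))
  tm1 <- tetra_mesh(reg, matrix(1:4, 1))
  qs <- quality_summary(tm1)
  expect_equal(qs$mean, 1)
  expect_true(is.na(qs$sd) || qs$sd == 0)
  expect_equal(qs$n_elements, 1)
  expect_equal(qs$frac_below, 0)
  # concatenation: count-weighted mean
  corner <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  tm2 <- tetra_mesh(rbind(reg, corner + 5), rbind(1:4, 5:8))
  qs2 <- quality_summary(tm2)
  expect_equal(qs2$mean, (1 + sqrt(2) / 2) / 2, tolerance = 1e-9)
  expect_equal(sum(qs2$histogram$count), 2)
})

test_that("positively oriented tets are enforced by the container", {
  bad <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, -1))
  expect_error(tetra_mesh(bad, matrix(1:4, 1)), "orient")
})
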