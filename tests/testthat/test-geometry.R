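# Slice-pose algebra: plane intersections, rigid transforms as a group
# action, contour lifting, and exact point-to-surface distances.

test_that("plane intersection matches analytic solutions", {
  pz <- plane_z0()
  px <- plane_from_normal(c(1, 0, 0))
  l <- plane_intersection_line(pz, px)
  expect_false(is.null(l))
  expect_lt(min(abs(sum(l$direction * c(0, 1, 0))) - 1, 0) * -1, 1e-9)
  expect_lt(abs(l$point[1]), 1e-9)
  expect_lt(abs(l$point[3]), 1e-9)

  # parallel planes
  pz8 <- plane_z0()
  pz8$origin[3] <- 8
  expect_null(plane_intersection_line(pz, pz8))

  # oblique plane with normal (1,0,1)/sqrt(2) through the origin: solving the
  # two plane equations z = 0 and x + z = 0 gives the y-axis
  pob <- plane_from_normal(c(1, 0, 1))
  l2 <- plane_intersection_line(pz, pob)
  expect_equal(abs(sum(l2$direction * c(0, 1, 0))), 1, tolerance = 1e-9)
  expect_lt(sqrt(l2$point[1]^2 + l2$point[3]^2), 1e-9)

  # residual: returned line lies in both planes
  for (t in c(-40, 0, 40)) {
    p <- l2$point + t * l2$direction
    expect_lt(abs(sum((p - pz$origin) * plane_normal(pz))), 1e-6)
    expect_lt(abs(sum((p - pob$origin) * plane_normal(pob))), 1e-6)
  }

  # symmetry up to orientation
  l3 <- plane_intersection_line(pob, pz)
  expect_equal(abs(sum(l2$direction * l3$direction)), 1, tolerance = 1e-9)
})

test_that("malformed plane axes are rejected", {
  expect_error(slice_plane(c(0, 0, 0), c(1, 0, 0), c(0.5, 0.5, 0), c(1, 1), c(8, 8)),
               "orthogonal|unit")
  expect_error(slice_plane(c(0, 0, 0), c(2, 0, 0), c(0, 1, 0), c(1, 1), c(8, 8)),
               "unit")
  expect_error(slice_plane(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(-1, 1), c(8, 8)),
               "positive")
})

test_that("apply_rigid: identity, in-plane shift, and 90-degree rotation", {
  p <- plane_from_normal(c(0.2, -0.4, 1), origin = c(3, -2, 7))
  expect_identical(apply_rigid(p, rigid_params()), p)

  ps <- apply_rigid(p, rigid_inplane(tx = 5))
  expect_equal(ps$origin, p$origin + 5 * p$u_axis, tolerance = 1e-12)
  expect_equal(ps$u_axis, p$u_axis)
  expect_identical(ps$pixels, p$pixels)

  # gamma = 90 deg about the grid centre: the material point at centre + 2*u
  # follows the frame (lands on centre + 2*u'), and a 90-degree turn about the
  # normal maps the old u axis onto the old v axis (Rodrigues matrix oracle)
  ctr <- plane_grid_center(p)
  pr <- apply_rigid(p, rigid_inplane(gamma = 90))
  af <- rigid_to_affine(rigid_inplane(gamma = 90), p)
  moved <- as.numeric(af$R %*% (ctr + 2 * p$u_axis) + af$b)
  n <- plane_normal(p)
  ang <- 90 * pi / 180
  K <- matrix(c(0, -n[3], n[2], n[3], 0, -n[1], -n[2], n[1], 0), 3, byrow = TRUE)
  Rot <- diag(3) + sin(ang) * K + (1 - cos(ang)) * K %*% K   # Rodrigues oracle
  expect_equal(moved, as.numeric(Rot %*% (2 * p$u_axis)) + ctr, tolerance = 1e-9)
  expect_equal(moved, ctr + 2 * pr$u_axis, tolerance = 1e-9)
  expect_equal(moved, ctr + 2 * p$v_axis, tolerance = 1e-9)
})

test_that("rigid transforms form a group action with exact inverses", {
  set.seed(7)
  p <- plane_from_normal(c(0.3, 0.5, 0.9), origin = c(-4, 2, 11))
  for (rep in 1:10) {
    t1 <- rigid_params(runif(1, -5, 5), runif(1, -5, 5), runif(1, -5, 5),
                       runif(1, -20, 20), runif(1, -20, 20), runif(1, -20, 20))
    t2 <- rigid_params(runif(1, -5, 5), runif(1, -5, 5), runif(1, -5, 5),
                       runif(1, -20, 20), runif(1, -20, 20), runif(1, -20, 20))
    seq_pose <- apply_rigid(apply_rigid(p, t1), t2)
    comp_pose <- apply_rigid(p, compose_rigid(t1, t2, p))
    expect_equal(seq_pose$origin, comp_pose$origin, tolerance = 1e-9)
    expect_equal(seq_pose$u_axis, comp_pose$u_axis, tolerance = 1e-9)
    expect_equal(seq_pose$v_axis, comp_pose$v_axis, tolerance = 1e-9)

    inv <- invert_rigid(t1, p)
    back <- apply_rigid(apply_rigid(p, t1), inv)
    expect_equal(back$origin, p$origin, tolerance = 1e-9)
    expect_equal(back$u_axis, p$u_axis, tolerance = 1e-9)
    expect_equal(back$v_axis, p$v_axis, tolerance = 1e-9)
  }
})

test_that("in-plane transforms must have zero out-of-plane components", {
  expect_error(rigid_params(tz = 1, inplane_only = TRUE), "in-plane|inplane")
  expect_error(rigid_params(alpha = 1, inplane_only = TRUE), "in-plane|inplane")
})

test_that("contour_to_3d round-trips and follows the pose formula", {
  # canonical axes: in-plane (1,2) -> (1,2,0)
  p <- slice_plane(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(1, 1), c(32, 32))
  cc <- labelled_contour("LV_ENDO", rbind(c(1, 2), c(4, 2), c(4, 6)), closed = TRUE)
  P3 <- contour_to_3d(cc, p)
  expect_equal(P3[1, ], c(1, 2, 0))

  # tilted plane: pixel (i, j) maps to origin + j*s_c*u + i*s_r*v
  pt <- plane_from_normal(c(1, 1, 1), origin = c(5, -3, 2), spacing = 0.7)
  i <- 3; j <- 11
  xy <- cbind(j * pt$spacing[1], i * pt$spacing[2])
  expect_equal(as.numeric(plane_to_world(pt, xy)),
               pt$origin + j * pt$spacing[1] * pt$u_axis + i * pt$spacing[2] * pt$v_axis,
               tolerance = 1e-12)

  # random contour round trip
  set.seed(11)
  pts <- matrix(runif(40, 0, 20), ncol = 2)
  cc2 <- labelled_contour("RV_ENDO", pts)
  back <- world_to_plane(pt, contour_to_3d(cc2, pt))
  expect_equal(back$xy, unname(pts), tolerance = 1e-9)
  expect_lt(max(abs(back$w)), 1e-9)
})

test_that("point-to-mesh distance is the exact triangle minimum", {
  tr <- fx_truth()
  mesh <- tr$lv_endo
  # a vertex of the mesh itself -> 0
  expect_equal(point_to_mesh_distance(mesh$vertices[10, , drop = FALSE], mesh), 0,
               tolerance = 1e-12)
  # point above the centroid of a large flat triangle -> its height
  flat <- surface_mesh(rbind(c(0, 0, 0), c(10, 0, 0), c(0, 10, 0)), rbind(1:3))
  expect_equal(point_to_mesh_distance(rbind(c(3, 3, 4.5)), flat), 4.5)
  # random points vs independent projection/clamping oracle
  set.seed(5)
  small <- surface_mesh(matrix(rnorm(3 * 20, sd = 10), ncol = 3),
                        matrix(sample(20, 36, replace = TRUE), ncol = 3),
                        check = FALSE)
  keep <- apply(small$triangles, 1, function(f) length(unique(f)) == 3)
  small$triangles <- small$triangles[keep, , drop = FALSE]
  pts <- matrix(rnorm(3 * 25, sd = 12), ncol = 3)
  expect_equal(point_to_mesh_distance(pts, small), oracle_point_mesh(pts, small),
               tolerance = 1e-9)
  expect_error(point_to_mesh_distance(pts, surface_mesh(matrix(0, 1, 3),
                                                        matrix(integer(0), 0, 3))),
               "empty")
})
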