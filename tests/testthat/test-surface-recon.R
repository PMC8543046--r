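# Surface reconstruction: lofting, iterative TPS fitting, intersection
# resolution and the basal join.

.circle3 <- function(r, z, n = 40) {
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  cbind(r * cos(th), r * sin(th), z)
}

test_that("lofting stacked circles gives cylinders and cones", {
  loops <- lapply(seq(0, 40, by = 8), function(z) .circle3(15, z))
  m <- init_surface(loops, axis = c(0, 0, 1), n_theta = 36)
  expect_length(mesh_boundary_loops(m), 1)            # one open basal boundary
  r <- sqrt(rowSums(m$vertices[, 1:2]^2))
  mid <- abs(m$vertices[, 3] - 20) <= 4
  expect_lt(max(abs(r[mid] - 15)), 0.2)
  # apex extrapolated half a gap below the lowest loop
  expect_equal(min(m$vertices[, 3]), -4, tolerance = 1e-6)

  cone_loops <- lapply(1:5, function(k) .circle3(26 - 4 * k, 8 * k))
  mc <- init_surface(cone_loops, axis = c(0, 0, 1))
  expect_lt(min(mc$vertices[, 3]), 8)                 # apex below lowest loop

  expect_error(init_surface(loops[1], axis = c(0, 0, 1)), "2 stacked")
})

test_that("the apex comes from the lowest LAX point when available", {
  loops <- lapply(seq(10, 40, by = 10), function(z) .circle3(15, z))
  lax <- rbind(c(0, 0, -3), c(2, 1, 5), c(14, 0, 20))
  m <- init_surface(loops, axis = c(0, 0, 1), lax_points = lax)
  expect_equal(min(m$vertices[, 3]), -3, tolerance = 1e-9)
})

test_that("TPS fitting pulls an offset sphere onto sampled contours", {
  target <- make_phantom_surfaces(phantom_spec_lv_only(c(30, 30, 30), base_height = Inf),
                                  ring_spacing = 1.2)$lv_endo
  init <- make_phantom_surfaces(phantom_spec_lv_only(c(25, 25, 25), base_height = Inf),
                                ring_spacing = 1.2)$lv_endo
  # contour rings sampled from the target sphere
  cons <- do.call(rbind, lapply(seq(-25, 25, by = 5), function(z)
    .circle3(sqrt(900 - z^2), z, 60)))
  fit <- fit_surface(init, cons, n_iter = 10)
  r <- sqrt(rowSums(fit$vertices^2))
  expect_lt(mean(abs(r - 30)), 0.2)
  # residual trace non-increasing within a 5% slack
  tr <- attr(fit, "residual_trace")
  expect_true(all(diff(tr) <= 0.05 * head(tr, -1) + 1e-9))
})

test_that("disjoint nested surfaces pass through intersection resolution", {
  outer <- make_phantom_surfaces(phantom_spec_lv_only(c(20, 20, 20), base_height = Inf),
                                 ring_spacing = 1.0)$lv_endo
  inner <- outer
  inner$vertices <- inner$vertices * 0.7
  res <- resolve_intersections(inner, outer)
  expect_equal(res$crossings, 0)
  expect_equal(res$endo$vertices, inner$vertices)   # untouched (idempotent)
  expect_equal(res$epi$vertices, outer$vertices)
})

test_that("a protruding bump is pushed back inside the outer surface", {
  outer <- make_phantom_surfaces(phantom_spec_lv_only(c(20, 20, 20), base_height = Inf),
                                 ring_spacing = 1.0)$lv_endo
  inner <- outer
  inner$vertices <- inner$vertices * 0.85
  k <- order(inner$vertices[, 3])[1:14]
  inner$vertices[k, ] <- inner$vertices[k, ] * 1.35   # bump through the outer wall
  expect_gt(mesh_crossings(inner, outer), 0)
  res <- resolve_intersections(inner, outer)
  expect_equal(res$crossings, 0)
  # no vertex of the resolved inner surface outside the outer (signed audit)
  expect_true(all(mesh_inside(res$endo$vertices, mesh_bvh(res$epi))))
})

test_that("the basal join stitches concentric cylinders watertight", {
  loops_o <- lapply(seq(0, 40, by = 8), function(z) .circle3(20, z))
  loops_i <- lapply(seq(0, 40, by = 8), function(z) .circle3(10, z))
  epi <- init_surface(loops_o, axis = c(0, 0, 1), label = "EPI")
  lv <- init_surface(loops_i, axis = c(0, 0, 1), label = "LV_ENDO")
  bv <- join_at_base(lv, NULL, epi, basal_point = c(0, 0, 40), axis = c(0, 0, 1))
  expect_true(mesh_is_watertight(bv))
  # Euler characteristic of the closed solid boundary is 2 (a sphere)
  Vn <- nrow(bv$vertices)
  En <- nrow(unique(cinemesh:::.mesh_edges(bv$triangles)))
  Fn <- nrow(bv$triangles)
  expect_equal(Vn - En + Fn, 2)
})

test_that("full reconstruction encloses the analytic wall volume", {
  spec <- fx_spec()
  recon <- reconstruct_surfaces(fx_planes(), fx_contours())
  expect_true(mesh_is_watertight(recon$biventricular))
  vol <- mesh_volume(recon$biventricular)
  # analytic myocardial volume below the reconstructed basal plane by MC
  imp <- phantom_implicits(spec)
  zb <- sum(recon$basal_point * recon$axis)
  wall <- function(p) {
    imp$heart(p) < 0 & imp$lv_endo(p) >= 0 & imp$rv_cavity(p) >= 0 &
      p[, 3] <= min(zb, spec$base_height)
  }
  vtrue <- oracle_mc_volume(wall, c(-40, -35, -65), c(60, 35, 34), n = 6e5)
  expect_equal(vol, vtrue, tolerance = 0.10)
  # reconstruction is deterministic: identical inputs give identical meshes
  recon2 <- reconstruct_surfaces(fx_planes(), fx_contours())
  expect_identical(recon$biventricular$vertices, recon2$biventricular$vertices)
})

test_that("the final fit is at least as close to the contours as the loft", {
  planes <- fx_planes()
  cons <- fx_contours()
  inj <- inject_misalignment(planes, list(tx = c(-3, 3), ty = c(-3, 3),
                                          gamma = c(-5, 5)), seed = 5)
  resB <- correct_contours(inj$planes, cons, max_sweeps = 3, restart = FALSE)
  recon <- reconstruct_surfaces(inj$planes, cons, resB$thetas)
  pt <- mapply(apply_rigid, inj$planes, resB$thetas, SIMPLIFY = FALSE)
  pts <- do.call(rbind, lapply(seq_along(pt), function(k)
    do.call(rbind, lapply(cons[[k]], contour_to_3d, plane = pt[[k]]))))
  final_d <- mean(point_to_mesh_distance(pts, recon$biventricular))
  for (s in c("lv_endo", "rv_endo", "epi")) {
    tr <- recon$residuals[[s]]
    expect_lte(min(tr), tr[1] + 1e-9)          # fit no worse than the loft
  }
  expect_lt(final_d, 1.3672)                   # within the in-plane resolution
})
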