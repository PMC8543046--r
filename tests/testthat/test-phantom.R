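# Synthetic biventricular phantom: analytic surfaces, slicing, contours,
# misalignment injection.

test_that("degenerate sphere phantom matches closed forms", {
  sp <- phantom_spec_lv_only(c(25, 25, 25), base_height = Inf)
  s <- make_phantom_surfaces(sp, ring_spacing = 1.0)
  expect_true(mesh_is_watertight(s$lv_endo))
  expect_equal(mesh_area(s$lv_endo), 4 * pi * 25^2, tolerance = 0.01)
  expect_equal(mesh_volume(s$lv_endo), 4 / 3 * pi * 25^3, tolerance = 0.01)
})

test_that("LV endocardial volume matches the ellipsoid formula", {
  sp <- phantom_spec_lv_only(c(20, 24, 30), base_height = Inf)
  s <- make_phantom_surfaces(sp, ring_spacing = 1.0)
  expect_equal(mesh_volume(s$lv_endo), 4 / 3 * pi * 20 * 24 * 30, tolerance = 0.01)
})

test_that("default phantom surfaces are watertight with the apex lowest", {
  s <- fx_truth()
  expect_true(mesh_is_watertight(s$lv_endo))
  expect_true(mesh_is_watertight(s$epi))
  expect_true(mesh_is_watertight(s$rv_endo))
  apex <- s$lv_endo$vertices[which.min(s$lv_endo$vertices[, 3]), ]
  expect_equal(apex[3], -fx_spec()$lv_semi_axes[3], tolerance = 1e-6)
  # surface vertices sit on the analytic zero level sets
  below <- s$epi$vertices[, 3] < fx_spec()$base_height - 1e-6
  expect_lt(max(abs(s$implicits$heart(s$epi$vertices[below, ]))), 0.2)
})

test_that("degenerate specs are rejected", {
  expect_error(phantom_spec(rv_offset = c(200, 0, 0)), "overlap")
  expect_error(phantom_spec(rv_offset = c(0, 0, 0), rv_semi_axes = c(5, 5, 5)),
               "inside")
  expect_error(phantom_spec(intensity = c(background = 1, myocardium = 1, blood = 2)),
               "distinct")
})

test_that("slice_phantom fills pixels from regions, reproducibly", {
  spec <- fx_spec()
  # a plane far outside the phantom: all-background mask
  far <- plane_z0(n = 16)
  far$origin[3] <- 500
  out <- slice_phantom(spec, far)
  expect_true(all(out$mask == 0L))

  # bit-identical re-run with the same seed
  p <- fx_planes()[[6]]
  s1 <- slice_phantom(spec, p)
  s2 <- slice_phantom(spec, p)
  expect_identical(s1$plane$pixels, s2$plane$pixels)
  expect_identical(s1$mask, s2$mask)

  # noiseless mid-ventricular SAX: LV cavity pixel area vs analytic section
  spec0 <- spec
  spec0$noise_sd <- 0
  m <- slice_phantom(spec0, p)$mask
  z <- p$origin[3]
  a <- spec$lv_semi_axes
  area_true <- pi * a[1] * a[2] * (1 - (z / a[3])^2)
  expect_equal(sum(m == 1L) * prod(p$spacing), area_true, tolerance = 0.02)
})

test_that("analytic contours sit exactly on the implicit surfaces", {
  spec <- fx_spec()
  imp <- phantom_implicits(spec)
  p <- fx_planes()[[6]]
  cons <- analytic_contours(spec, p)
  expect_setequal(unique(vapply(cons, `[[`, character(1), "label")),
                  c("LV_ENDO", "LV_EPI", "RV_ENDO", "SEPTUM", "RV_EPI"))
  fmap <- list(LV_ENDO = imp$lv_endo, LV_EPI = imp$lv_epi, SEPTUM = imp$lv_epi,
               RV_ENDO = imp$rv_endo, RV_EPI = imp$rv_epi)
  for (cc in cons) {
    P3 <- contour_to_3d(cc, p)
    expect_lt(max(abs(fmap[[cc$label]](P3))), 1e-6)
    # arc spacing at most 0.5 mm
    seg <- sqrt(rowSums(diff(P3)^2))
    expect_lt(max(seg), 0.51)
  }
  # the SAX LV endocardial contour is closed
  lv <- cons[[which(vapply(cons, `[[`, character(1), "label") == "LV_ENDO")[1]]]
  expect_true(lv$closed)
})

test_that("contours of a spherical phantom are circles of known radius", {
  sp <- phantom_spec_lv_only(c(20, 20, 20), base_height = Inf)
  p <- plane_z0(n = 64, spacing = 1)
  cons <- analytic_contours(sp, p)
  lv <- cons[[which(vapply(cons, `[[`, character(1), "label") == "LV_ENDO")[1]]]
  P3 <- contour_to_3d(lv, p)
  r <- sqrt(rowSums(P3[, 1:2]^2))
  expect_lt(max(abs(r - 20)), 1e-3)
})

test_that("a plane tangent to the apex yields no crash", {
  sp <- phantom_spec_lv_only(c(20, 20, 20), base_height = Inf)
  p <- plane_z0(n = 64)
  p$origin[3] <- -20 + 1e-5
  expect_no_error(cons <- analytic_contours(sp, p))
  p$origin[3] <- -40   # below the epicardial shell entirely
  expect_length(analytic_contours(sp, p), 0)
})

test_that("contours lie on the ground-truth meshes within the mesh bound", {
  s <- make_phantom_surfaces(fx_spec(), ring_spacing = 1.0, n_theta = 160)
  p <- fx_planes()[[5]]
  mmap <- list(LV_ENDO = s$lv_endo, LV_EPI = s$epi, RV_EPI = s$epi,
               SEPTUM = s$rv_endo, RV_ENDO = s$rv_endo)
  for (cc in analytic_contours(fx_spec(), p)) {
    d <- point_to_mesh_distance(contour_to_3d(cc, p), mmap[[cc$label]])
    expect_lt(max(d), 0.25)
  }
})

test_that("misalignment injection is exact, seeded, and invertible", {
  planes <- fx_planes()
  # all-zero ranges leave every pose unchanged
  inj0 <- inject_misalignment(planes, list(tx = c(0, 0), ty = c(0, 0),
                                           gamma = c(0, 0)), seed = 3)
  expect_identical(inj0$planes[[4]]$origin, planes[[4]]$origin)

  # a degenerate range produces an exact shift
  inj5 <- inject_misalignment(planes[1], list(tx = c(5, 5), ty = c(0, 0),
                                              gamma = c(0, 0)), seed = 3)
  expect_equal(inj5$planes[[1]]$origin, planes[[1]]$origin + 5 * planes[[1]]$u_axis,
               tolerance = 1e-12)

  # determinism across runs
  rg <- list(tx = c(-5, 5), ty = c(-5, 5), gamma = c(-7, 7), tz = c(-3, 3))
  a <- inject_misalignment(planes, rg, seed = 17)
  b <- inject_misalignment(planes, rg, seed = 17)
  expect_identical(a$truth, b$truth)

  # applying the exact inverse restores the original poses
  for (k in c(1, 8, 15)) {
    inv <- invert_rigid(a$truth[[k]], planes[[k]])
    back <- apply_rigid(a$planes[[k]], inv)
    expect_equal(back$origin, planes[[k]]$origin, tolerance = 1e-9)
    expect_equal(back$u_axis, planes[[k]]$u_axis, tolerance = 1e-9)
  }
})

test_that("the phase family peaks at the requested phase", {
  fam <- phantom_phase_family(fx_spec(), n_phases = 6, peak_phase = 3)
  vols <- vapply(fam, function(s) prod(s$lv_semi_axes), numeric(1))
  expect_equal(which.max(vols), 3)
})
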