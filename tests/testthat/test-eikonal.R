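# Anisotropic Eikonal activation simulation and the epicardial comparison.

fx_ball_mesh <- function() {
  if (is.null(.fx$ball)) {
    sp <- make_phantom_surfaces(phantom_spec_lv_only(c(20, 20, 20), base_height = Inf),
                                ring_spacing = 1.0)$lv_endo
    .fx$ball <- tetrahedralize(sp, target_edge = 1.6)
  }
  .fx$ball
}

test_that("conduction tensors have the prescribed spectra and endo layer", {
  tm <- fx_ball_mesh()
  spec <- conduction_spec(v_fiber = 0.65, v_sheet = 0.4, v_normal = 0.25, roots = 1L)
  M <- build_speed_tensors(tm, spec)
  for (k in c(3, 500)) {
    Mk <- matrix(c(M[k, 1], M[k, 2], M[k, 3], M[k, 2], M[k, 4], M[k, 5],
                   M[k, 3], M[k, 5], M[k, 6]), 3, 3)
    expect_equal(sort(eigen(Mk)$values), sort(c(0.65, 0.4, 0.25)^2),
                 tolerance = 1e-9)
  }
  # equal speeds give the isotropic tensor
  spec_iso <- conduction_spec(v_fiber = 0.5, v_sheet = 0.5, v_normal = 0.5, roots = 1L)
  Mi <- build_speed_tensors(tm, spec_iso)
  expect_lt(max(abs(Mi[, c(2, 3, 5)])), 1e-12)
  expect_lt(max(abs(Mi[, c(1, 4, 6)] - 0.25)), 1e-12)
  # the endocardial layer is exactly isotropic (eigenvalue spread audit)
  endo_pts <- tm$vertices[abs(sqrt(rowSums(tm$vertices^2)) - 20) < 0.5, ]
  Me <- build_speed_tensors(tm, conduction_spec(roots = 1L, endo_thickness = 2),
                            endo_vertices = endo_pts)
  layer <- attr(Me, "endo_layer")
  expect_gt(sum(layer), 0)
  for (k in which(layer)[1:5]) {
    Mk <- matrix(c(Me[k, 1], Me[k, 2], Me[k, 3], Me[k, 2], Me[k, 4], Me[k, 5],
                   Me[k, 3], Me[k, 5], Me[k, 6]), 3, 3)
    expect_lt(diff(range(eigen(Mk)$values)), 1e-9)
  }
  expect_error(build_speed_tensors(tm, conduction_spec(roots = 1L,
                                                       fibers = matrix(0, nrow(tm$tets), 3))),
               "zero fiber")
})

test_that("isotropic activation matches the analytic distance and the
           Dijkstra bound", {
  tm <- fx_ball_mesh()
  root <- which.min(rowSums(sweep(tm$vertices, 2, c(0, 0, -20))^2))
  v <- 0.8
  am <- solve_eikonal(tm, v, root)
  expect_true(all(am$reached))
  expect_equal(am$times[root], 0)
  d <- sqrt(rowSums(sweep(tm$vertices, 2, tm$vertices[root, ])^2))
  rel <- abs(am$times * v - d) / pmax(d, 1e-9)
  far <- d > 5
  expect_lt(mean(rel[far]), 0.02)
  expect_lt(max(rel[far]), 0.05)
  # doubling all speeds halves all times exactly
  am2 <- solve_eikonal(tm, 2 * v, root)
  expect_equal(am2$times, am$times / 2, tolerance = 1e-12)
  # admissibility: never slower than the edge-graph shortest path
  e <- unique(rbind(tm$tets[, c(1, 2)], tm$tets[, c(1, 3)], tm$tets[, c(1, 4)],
                    tm$tets[, c(2, 3)], tm$tets[, c(2, 4)], tm$tets[, c(3, 4)]))
  w <- sqrt(rowSums((tm$vertices[e[, 1], ] - tm$vertices[e[, 2], ])^2)) / v
  g <- igraph::graph_from_edgelist(e, directed = FALSE)
  igraph::E(g)$weight <- w
  dg <- as.numeric(igraph::distances(g, v = root)[1, ])
  expect_true(all(am$times <= dg + 1e-6))
})

test_that("root offsets are kept exactly and causality holds", {
  tm <- fx_ball_mesh()
  roots <- c(1L, 200L)
  am <- solve_eikonal(tm, 0.6, roots, offsets = c(0, 5))
  expect_equal(am$times[1], 0)
  expect_lte(am$times[200], 5)  # may be reached earlier from the other root
  expect_true(all(am$times >= 0))
})

test_that("epicardial mapping pairs nearest neighbours deterministically", {
  tm <- fx_ball_mesh()
  root <- 1L
  am <- solve_eikonal(tm, 0.7, root)
  bnd <- cpp_tet_boundary(tm$tets, nrow(tm$vertices))
  epiv <- sort(unique(as.vector(bnd)))
  # reference points exactly at epicardial vertices: identity pairing
  ids <- epiv[seq(1, length(epiv), by = 7)]
  paired <- map_to_epicardium(am, tm, tm$vertices[ids, ], am$times[ids])
  expect_equal(paired$vertex, ids)
  expect_equal(paired$simulated, paired$reference)
  expect_equal(activation_correlation(paired), 1)
  # brute-force pairing oracle on jittered points
  set.seed(7)
  ref <- tm$vertices[ids[1:40], ] + matrix(rnorm(120, sd = 0.3), 40, 3)
  paired2 <- map_to_epicardium(am, tm, ref, rep(0, 40))
  EV <- tm$vertices[epiv, ]
  oracle <- vapply(seq_len(40), function(k)
    epiv[which.min(colSums((t(EV) - ref[k, ])^2))], integer(1))
  expect_equal(paired2$vertex, oracle)
  # exclusion mask drops points
  paired3 <- map_to_epicardium(am, tm, ref, rep(0, 40),
                               exclude = c(rep(TRUE, 10), rep(FALSE, 30)))
  expect_equal(nrow(paired3), 30)
  expect_error(map_to_epicardium(am, tm, matrix(0, 0, 3), numeric(0)), "empty")
})

test_that("correlation behaves like Pearson's r", {
  x <- c(1, 5, 9, 2, 7)
  expect_equal(activation_correlation(x, x), 1)
  expect_equal(activation_correlation(x, -x), -1)
  expect_equal(activation_correlation(x, 2 * x + 5), 1)
  expect_error(activation_correlation(c(1, 2), c(1, 2)), "3 pairs")
  expect_error(activation_correlation(x, rep(1, 5)), "variance")
})

test_that("a simulated map correlates with its own epicardial subsample", {
  tm <- fx_ball_mesh()
  root <- which.min(tm$vertices[, 3])
  spec <- conduction_spec(roots = root)
  bnd <- cpp_tet_boundary(tm$tets, nrow(tm$vertices))
  epiv <- sort(unique(as.vector(bnd)))
  M <- build_speed_tensors(tm, spec, endo_vertices = NULL)
  am <- solve_eikonal(tm, M, spec)
  set.seed(11)
  ids <- sample(epiv, 200)
  ref <- tm$vertices[ids, ] + matrix(rnorm(600, sd = 0.2), 200, 3)
  paired <- map_to_epicardium(am, tm, ref, am$times[ids])
  expect_gt(activation_correlation(paired), 0.99)
})

test_that("activation converges under mesh refinement", {
  sp <- make_phantom_surfaces(phantom_spec_lv_only(c(15, 15, 15), base_height = Inf),
                              ring_spacing = 0.8)$lv_endo
  tm1 <- tetrahedralize(sp, target_edge = 2.4)
  tm2 <- tetrahedralize(sp, target_edge = 1.2)
  root_pos <- c(0, 0, -15)
  r1 <- which.min(rowSums(sweep(tm1$vertices, 2, root_pos)^2))
  r2 <- which.min(rowSums(sweep(tm2$vertices, 2, root_pos)^2))
  a1 <- solve_eikonal(tm1, 0.7, r1)
  a2 <- solve_eikonal(tm2, 0.7, r2)
  # compare on the coarse vertices via nearest fine vertex
  nn <- vapply(seq_len(nrow(tm1$vertices)), function(k)
    which.min(colSums((t(tm2$vertices) - tm1$vertices[k, ])^2)), integer(1))
  keep <- a1$times > 5
  rms <- sqrt(mean(((a1$times - a2$times[nn])[keep] / a1$times[keep])^2))
  expect_lt(rms, 0.02)
})

test_that("the conduction grid sweep returns the best correlating settings", {
  tm <- fx_ball_mesh()
  root <- which.min(tm$vertices[, 3])
  spec_true <- conduction_spec(v_fiber = 0.65, v_endo = 1.2, roots = root)
  M <- build_speed_tensors(tm, spec_true)
  am <- solve_eikonal(tm, M, spec_true)
  bnd <- cpp_tet_boundary(tm$tets, nrow(tm$vertices))
  epiv <- sort(unique(as.vector(bnd)))
  set.seed(3)
  ids <- sample(epiv, 150)
  cal <- calibrate_conduction(tm, tm$vertices[ids, ], am$times[ids],
                              v_fiber_grid = c(0.5, 0.65),
                              v_endo_grid = 1.2,
                              spec = spec_true)
  expect_gt(cal$r, 0.99)
  expect_equal(nrow(cal$table), 2)
})
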