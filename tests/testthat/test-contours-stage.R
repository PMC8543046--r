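# Contour crossings and the stage-B contours-based correction.

test_that("contour crossings match closed forms and a brute-force oracle", {
  p <- plane_z0(n = 64)
  ctr <- plane_grid_center(p)
  circ <- circle_contour(p, radius = 5)
  # a diameter line through the circle centre: two crossings, 10 mm apart
  line <- line3d(ctr, p$u_axis)
  cr <- contour_crossings(circ, p, line)
  expect_equal(nrow(cr$points), 2)
  expect_equal(sqrt(sum((cr$points[2, ] - cr$points[1, ])^2)), 10, tolerance = 1e-6)
  expect_true(all(diff(cr$t) > 0))

  # a line missing the contour entirely
  far <- line3d(ctr + 20 * p$v_axis, p$u_axis)
  expect_equal(nrow(contour_crossings(circ, p, far)$points), 0)

  # random polygon vs per-segment brute force
  set.seed(51)
  for (rep in 1:5) {
    pts <- cbind(runif(12, 5, 55), runif(12, 5, 55))
    poly <- labelled_contour("LV_EPI", pts, closed = TRUE)
    dir2 <- c(cos(runif(1, 0, pi)), sin(runif(1, 0, pi)))
    orig2 <- c(runif(1, 10, 50), runif(1, 10, 50))
    line <- line3d(plane_to_world(p, rbind(orig2)),
                   dir2[1] * p$u_axis + dir2[2] * p$v_axis)
    cr <- contour_crossings(poly, p, line)
    # oracle: explicit segment/line intersection in 2D
    hits <- list()
    n <- nrow(pts)
    for (k in seq_len(n)) {
      a <- pts[k, ]; b <- pts[k %% n + 1, ]
      sa <- (a[1] - orig2[1]) * dir2[2] - (a[2] - orig2[2]) * dir2[1]
      sb <- (b[1] - orig2[1]) * dir2[2] - (b[2] - orig2[2]) * dir2[1]
      if ((sa <= 0 && sb > 0) || (sa > 0 && sb <= 0)) {
        f <- sa / (sa - sb)
        hits[[length(hits) + 1L]] <- a + f * (b - a)
      }
    }
    H <- do.call(rbind, hits)
    nh <- if (is.null(H)) 0L else nrow(H)
    expect_equal(nrow(cr$points), nh)
    expect_equal(nrow(cr$points) %% 2, 0)   # closed contour: even count
    if (nh > 0) {
      got <- world_to_plane(p, cr$points)$xy
      ord <- order(got[, 1], got[, 2]); ord2 <- order(H[, 1], H[, 2])
      expect_equal(got[ord, ], H[ord2, ], tolerance = 1e-9)
    }
  }
})

test_that("pair dissimilarity is symmetric, zero at truth, positive under shift", {
  planes <- fx_planes()
  cons <- fx_contours()
  i <- 6; j <- 14
  e <- contour_pair_dissimilarity(planes[[i]], cons[[i]], planes[[j]], cons[[j]])
  expect_lt(e, 0.1)   # analytic contours coincide at crossings
  e_sym <- contour_pair_dissimilarity(planes[[j]], cons[[j]], planes[[i]], cons[[i]])
  expect_equal(e, e_sym, tolerance = 1e-9)

  # translate slice j along the intersection line: matched distances grow
  line <- plane_intersection_line(planes[[i]], planes[[j]])
  d_in <- c(sum(line$direction * planes[[j]]$u_axis),
            sum(line$direction * planes[[j]]$v_axis))
  pj <- apply_rigid(planes[[j]], rigid_inplane(tx = 3 * d_in[1], ty = 3 * d_in[2]))
  e_shift <- contour_pair_dissimilarity(planes[[i]], cons[[i]], pj, cons[[j]])
  expect_gt(e_shift, e + 0.5)

  # slices sharing no labels are skipped
  only_rvepi <- Filter(function(cc) cc$label == "RV_EPI", cons[[i]])
  expect_true(is.na(contour_pair_dissimilarity(planes[[i]], only_rvepi,
                                               planes[[j]], cons[[j]])))
})

test_that("the C++ fast path agrees with the reference dissimilarity", {
  planes <- fx_planes()
  cons <- fx_contours()
  set.seed(61)
  for (rep in 1:10) {
    i <- sample(1:12, 1); j <- sample(13:16, 1)
    pa <- apply_rigid(planes[[i]], rigid_inplane(runif(1, -4, 4), runif(1, -4, 4),
                                                 runif(1, -6, 6)))
    pb <- apply_rigid(planes[[j]], rigid_inplane(runif(1, -4, 4), runif(1, -4, 4),
                                                 runif(1, -6, 6)))
    eR <- contour_pair_dissimilarity(pa, cons[[i]], pb, cons[[j]])
    pi_ <- cinemesh:::.pack_contours(cons[[i]])
    pj_ <- cinemesh:::.pack_contours(cons[[j]])
    eC <- cpp_contour_pair_E(pa$origin, pa$u_axis, pa$v_axis,
                             pi_$pts, pi_$start, pi_$len, pi_$lab, pi_$closed,
                             pb$origin, pb$u_axis, pb$v_axis,
                             pj_$pts, pj_$start, pj_$len, pj_$lab, pj_$closed)
    expect_equal(eR, eC, tolerance = 1e-9)
  }
})

test_that("stage B reduces the crossing residual and the distance to the
           true surfaces on repeated seeded runs", {
  keep <- c(2, 4, 6, 8, 10, 12, 13, 14, 15, 16)   # reduced stack, full LAX fan
  planes <- fx_planes()[keep]
  cons <- fx_contours()[keep]
  truth <- fx_truth()
  bvhs <- list(LV_ENDO = mesh_bvh(truth$lv_endo), RV_ENDO = mesh_bvh(truth$rv_endo),
               EPI = mesh_bvh(truth$epi))
  smap <- c(LV_ENDO = "LV_ENDO", RV_ENDO = "RV_ENDO", SEPTUM = "RV_ENDO",
            LV_EPI = "EPI", RV_EPI = "EPI")
  truth_dist <- function(pl) {
    tot <- 0; m <- 0L
    for (k in seq_along(pl)) for (cc in cons[[k]]) {
      d <- point_to_mesh_distance(contour_to_3d(cc, pl[[k]]), bvhs[[smap[cc$label]]])
      tot <- tot + sum(d); m <- m + length(d)
    }
    tot / m
  }
  improved <- logical(20)
  improved_truth <- logical(20)
  for (s in 1:20) {
    inj <- inject_misalignment(planes, list(tx = c(-4.7, 4.7), ty = c(-4.7, 4.7),
                                            gamma = c(-6.6, 6.6)), seed = 100 + s)
    res <- correct_contours(inj$planes, cons, max_sweeps = 3, restart = FALSE)
    tab <- res$residuals
    before <- tab$mean[tab$stage == "before" & tab$label == "POOLED"]
    after <- tab$mean[tab$stage == "after" & tab$label == "POOLED"]
    improved[s] <- after < before
    corrected <- mapply(apply_rigid, inj$planes, res$thetas, SIMPLIFY = FALSE)
    improved_truth[s] <- truth_dist(corrected) < truth_dist(inj$planes)
  }
  expect_gte(mean(improved), 0.95)
  expect_true(all(improved_truth))
})

test_that("stage B recovers injected in-plane misalignments (gauge-fixed)", {
  planes <- fx_planes()
  cons <- fx_contours()
  inj <- inject_misalignment(planes, list(tx = c(-5, 5), ty = c(-5, 5),
                                          gamma = c(-7, 7)), seed = 77)
  res <- correct_contours(inj$planes, cons)
  # per-slice translation error after removing the best common rigid motion
  # between the recovered and true frames (three anchor points per slice)
  anchor <- function(p) rbind(plane_grid_center(p),
                              plane_grid_center(p) + 30 * p$u_axis,
                              plane_grid_center(p) + 30 * p$v_axis)
  X <- do.call(rbind, lapply(seq_along(planes), function(k)
    anchor(apply_rigid(inj$planes[[k]], res$thetas[[k]]))))
  Y <- do.call(rbind, lapply(planes, anchor))
  resid <- gauge_fixed_residual(X, Y)
  per_slice <- resid[seq(1, length(resid), by = 3)]  # the centre anchors
  expect_lt(median(per_slice), 0.7)
})
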