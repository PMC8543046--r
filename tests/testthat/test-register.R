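# Profile sampling, NCC, the global-motion objective and its optimiser.

test_that("profiles from identical coincident images agree sample by sample", {
  set.seed(31)
  img <- matrix(rnorm(40 * 40), 40, 40)
  pa <- plane_z0(n = 40, id = "a")
  pb <- plane_from_normal(c(1, 0, 0.2), origin = plane_grid_center(pa), n = 40, id = "b")
  # sample the same scalar field (via a shared function of position) on both
  f <- function(P) sin(P[, 1] / 3) + cos(P[, 2] / 4) + P[, 3] / 10
  ij <- expand.grid(i = 0:39, j = 0:39)
  mk <- function(p) matrix(f(plane_to_world(p, cbind(ij$j * p$spacing[1],
                                                     ij$i * p$spacing[2]))), 40, 40)
  pr <- sample_profiles(pa, pb, mk(pa), mk(pb), step = 0.5)
  expect_false(is.null(pr))
  expect_equal(pr$a, pr$b, tolerance = 0.02)   # bilinear on a smooth field

  # a line outside one image's extent: skip signal
  pc <- plane_from_normal(c(1, 0, 0), origin = c(500, 0, 0), n = 40)
  expect_null(sample_profiles(pa, pc, img, img, step = 0.5))
})

test_that("sampling a linear ramp is exact under bilinear interpolation", {
  pa <- plane_z0(n = 40, id = "a")
  pb <- plane_from_normal(c(0, 1, 0), origin = plane_grid_center(pa), n = 40, id = "b")
  ij <- expand.grid(i = 0:39, j = 0:39)
  ramp <- function(p) {
    W <- plane_to_world(p, cbind(ij$j * p$spacing[1], ij$i * p$spacing[2]))
    matrix(2 * W[, 1] + 0.5 * W[, 3] - 1, 40, 40)
  }
  pr <- sample_profiles(pa, pb, ramp(pa), ramp(pb), step = 0.31)
  pts <- outer(pr$t, as.numeric(plane_intersection_line(pa, pb)$direction))
  pts <- sweep(pts, 2, plane_intersection_line(pa, pb)$point, `+`)
  expect_equal(pr$a, 2 * pts[, 1] + 0.5 * pts[, 3] - 1, tolerance = 1e-9)
  expect_equal(pr$b, pr$a, tolerance = 1e-9)
})

test_that("ncc has the Pearson invariances", {
  x <- c(1, 2, 3, 4)
  expect_equal(ncc(x, x), 1)
  expect_equal(ncc(x, 2 * x), 1)                   # affine invariance
  expect_equal(ncc(x, c(2, 4, 6, 8)), 1)
  expect_equal(ncc(x, mean(x) - (x - mean(x))), -1)
  expect_true(is.na(ncc(x, rep(1, 4))))            # zero variance -> skip
  expect_true(is.na(ncc(1, 2)))
})

test_that("global motion sums admissible pairs and handles edge cases", {
  p1 <- plane_z0(id = "1")
  # single slice: empty pair set, GM = 0
  expect_equal(global_motion(list(p1), dissim = function(...) 0.5)$gm, 0)
  # stub dissimilarities add up
  p2 <- plane_from_normal(c(1, 0, 0), id = "2")
  p3 <- plane_from_normal(c(0, 1, 0), id = "3")
  stub <- function(pa, pb, da, db) {
    key <- paste(sort(c(pa$id, pb$id)), collapse = "")
    c("12" = 0.2, "13" = 0.3, "23" = NA_real_)[[key]]
  }
  gm <- global_motion(list(p1, p2, p3), dissim = stub)
  expect_equal(gm$gm, 0.5)
  expect_equal(gm$n_skipped, 1L)
  # no admissible pair at all: objective undefined
  expect_error(global_motion(list(p1, p2), dissim = function(...) NA_real_),
               "undefined")
})

test_that("the true poses attain the smallest GM among random perturbations", {
  spec <- fx_spec()
  idx <- c(3, 5, 7, 9, 13, 15)   # a reduced stack + two LAX views
  planes <- fx_planes()[idx]
  packed <- lapply(fx_contours()[idx], cinemesh:::.pack_contours)
  dissim <- function(pa, pb, ca, cb)
    cpp_contour_pair_E(pa$origin, pa$u_axis, pa$v_axis,
                       ca$pts, ca$start, ca$len, ca$lab, ca$closed,
                       pb$origin, pb$u_axis, pb$v_axis,
                       cb$pts, cb$start, cb$len, cb$lab, cb$closed)
  gm0 <- global_motion(planes, NULL, dissim, packed)$gm
  set.seed(41)
  worse <- vapply(1:100, function(r) {
    thetas <- replicate(length(planes),
                        rigid_inplane(runif(1, -4, 4), runif(1, -4, 4),
                                      runif(1, -6, 6)),
                        simplify = FALSE)
    global_motion(planes, thetas, dissim, packed)$gm
  }, numeric(1))
  expect_true(all(worse > gm0))
})

test_that("GM is invariant under a common rigid motion of all slices", {
  idx <- c(4, 6, 8, 13, 14)
  planes <- fx_planes()[idx]
  packed <- lapply(fx_contours()[idx], cinemesh:::.pack_contours)
  dissim <- function(pa, pb, ca, cb)
    cpp_contour_pair_E(pa$origin, pa$u_axis, pa$v_axis,
                       ca$pts, ca$start, ca$len, ca$lab, ca$closed,
                       pb$origin, pb$u_axis, pb$v_axis,
                       cb$pts, cb$start, cb$len, cb$lab, cb$closed)
  set.seed(13)
  thetas <- replicate(length(planes),
                      rigid_inplane(runif(1, -3, 3), runif(1, -3, 3), runif(1, -5, 5)),
                      simplify = FALSE)
  gm1 <- global_motion(planes, thetas, dissim, packed)$gm
  # one common rigid motion applied on top of every pose (gauge freedom)
  common <- list(R = cinemesh:::.axis_rotation(c(0.3, 0.5, 0.81), 17),
                 b = c(4, -7, 2.5))
  moved <- mapply(function(p, th) {
    pt <- apply_rigid(p, th)
    pt$origin <- as.numeric(common$R %*% pt$origin + common$b)
    pt$u_axis <- as.numeric(common$R %*% pt$u_axis)
    pt$v_axis <- as.numeric(common$R %*% pt$v_axis)
    pt
  }, planes, thetas, SIMPLIFY = FALSE)
  gm2 <- global_motion(moved, NULL, dissim, packed)$gm
  expect_equal(gm1, gm2, tolerance = 1e-9)
})

test_that("the optimiser is a fixed point on aligned slices and recovers a
           single perturbed slice", {
  spec <- fx_spec()
  idx <- c(2, 4, 6, 8, 10, 13, 14, 15, 16)
  planes <- fx_planes()[idx]
  contours <- fx_contours()[idx]
  # aligned phantom: thetas stay near zero, GM unchanged within tolerance
  res0 <- correct_contours(planes, contours, max_sweeps = 3)
  for (th in res0$thetas) {
    expect_lt(abs(th$tx), 0.5)
    expect_lt(abs(th$ty), 0.5)
    expect_lt(abs(th$gamma), 0.5)
  }
  # GM trace is non-increasing
  expect_true(all(diff(res0$gm_trace) <= 1e-9))

  # one slice perturbed: recovered within half a pixel and one degree
  pert <- planes
  pert[[3]] <- apply_rigid(planes[[3]], rigid_inplane(tx = 4, gamma = 5))
  res1 <- correct_contours(pert, contours)
  rec <- apply_rigid(pert[[3]], res1$thetas[[3]])
  expect_lt(sqrt(sum((rec$origin - planes[[3]]$origin)^2)), 0.7)
  ang <- acos(min(1, sum(rec$u_axis * planes[[3]]$u_axis))) * 180 / pi
  expect_lt(ang, 1)
})

test_that("the in-plane correction (intensity initialisation + contours)
           recovers injected misalignment to within a pixel", {
  spec <- fx_spec()
  planes <- fx_planes()
  cons <- fx_contours()
  imgs <- lapply(planes, function(p) slice_phantom(spec, p)$plane)
  inj <- inject_misalignment(imgs, list(tx = c(-5, 5), ty = c(-5, 5),
                                        gamma = c(-7, 7)), seed = 55)
  resA <- correct_intensity(inj$planes)
  # the intensity stage's role is a robust coarse initialisation: it must
  # reduce the gauge-invariant slice inconsistency (crossing residual) ...
  xres <- function(th) {
    tab <- cinemesh:::.crossing_residual_table(inj$planes, cons, th)
    tab$mean[tab$label == "POOLED"]
  }
  expect_lt(xres(resA$thetas), xres(NULL))
  # ... and the full in-plane correction it initialises reaches sub-pixel
  # gauge-fixed accuracy
  resB <- correct_contours(inj$planes, cons, thetas0 = resA$thetas)
  anchor <- function(p) rbind(plane_grid_center(p),
                              plane_grid_center(p) + 30 * p$u_axis,
                              plane_grid_center(p) + 30 * p$v_axis)
  X <- do.call(rbind, lapply(seq_along(planes), function(k)
    anchor(apply_rigid(inj$planes[[k]], resB$thetas[[k]]))))
  Y <- do.call(rbind, lapply(imgs, anchor))
  resid <- gauge_fixed_residual(X, Y)
  per_slice <- resid[seq(1, length(resid), by = 3)]
  expect_lt(median(per_slice), 1.3672)   # one pixel
})
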