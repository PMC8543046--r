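# Slice classification, phase selection, mask-based contour extraction with
# septum identification, and synthetic RV epicardium.

test_that("classify_slices separates parallel stacks from cross-sections", {
  stack <- lapply(1:10, function(k) {
    p <- plane_z0(id = sprintf("p%d", k))
    p$origin[3] <- 8 * k
    p
  })
  oblique <- lapply(1:3, function(k) plane_from_normal(c(1, k, 0), id = sprintf("o%d", k)))
  lay <- classify_slices(c(stack, oblique))
  expect_length(lay$sax, 10)
  expect_length(lay$lax, 3)
  # SAX ordering strictly monotone along the shared normal
  proj <- vapply(lay$sax, function(p) sum(p$origin * lay$sax_normal), numeric(1))
  expect_true(all(diff(proj) > 0))

  # permutation invariance of the grouping
  perm <- sample(13)
  lay2 <- classify_slices(c(stack, oblique)[perm])
  expect_length(lay2$sax, 10)
  expect_setequal(vapply(lay2$sax, `[[`, character(1), "id"),
                  vapply(lay$sax, `[[`, character(1), "id"))
})

test_that("the phantom layout yields 12 SAX and 4 LAX", {
  lay <- classify_slices(fx_planes())
  expect_length(lay$sax, 12)
  expect_length(lay$lax, 4)
})

test_that("all-parallel input warns about missing LAX", {
  stack <- lapply(1:5, function(k) { p <- plane_z0(); p$origin[3] <- k; p })
  expect_warning(lay <- classify_slices(stack), "LAX")
  expect_length(lay$lax, 0)
})

test_that("too few parallel planes is a classification error", {
  ps <- list(plane_z0(), plane_from_normal(c(1, 0, 0)), plane_from_normal(c(0, 1, 0)))
  expect_error(classify_slices(ps), "parallel")
})

test_that("lv_volume is pixel area times gap", {
  expect_equal(lv_volume(matrix(0L, 4, 4), c(1, 1), 8), 0)
  m <- matrix(0L, 20, 20)
  m[1:10, 1:10] <- 1L
  expect_equal(lv_volume(m, c(1, 1), 8), 100 * 8)
  # phantom noiseless stack against the analytic cavity volume
  spec <- fx_spec()
  spec$noise_sd <- 0
  lay <- classify_slices(fx_planes())
  masks <- lapply(lay$sax, function(p) slice_phantom(spec, p)$mask)
  v <- lv_volume(masks, lapply(lay$sax, `[[`, "spacing"), 8)
  imp <- phantom_implicits(spec)
  vtrue <- oracle_mc_volume(function(p) imp$lv_endo(p) < 0 & p[, 3] <= spec$base_height,
                            c(-26, -26, -55), c(26, 26, 33))
  expect_equal(v, vtrue, tolerance = 0.05)
})

test_that("phase selection picks the volume extrema with the tie rule", {
  expect_equal(select_phase(c(100, 80, 60, 90)), list(ed = 1L, es = 3L))
  expect_equal(select_phase(c(50, 50, 50)), list(ed = 1L, es = 1L))
  expect_error(select_phase(numeric(0)), "phase")
  fam <- phantom_phase_family(fx_spec(), n_phases = 5, peak_phase = 3)
  vols <- vapply(fam, function(s) prod(s$lv_semi_axes), numeric(1))
  expect_equal(select_phase(vols)$ed, 3L)
})

test_that("masks_to_contours extracts labelled sub-pixel boundaries", {
  p <- plane_z0(n = 60)
  # concentric disk-in-annulus: closed LV endo + closed LV epi, no septum
  ij <- expand.grid(i = 0:59, j = 0:59)
  r <- sqrt((ij$i - 30)^2 + (ij$j - 30)^2)
  mask <- matrix(0L, 60, 60)
  mask[r < 10] <- 1L
  mask[r >= 10 & r < 18] <- 2L
  cons <- masks_to_contours(mask, p)
  labs <- vapply(cons, `[[`, character(1), "label")
  expect_setequal(unique(labs), c("LV_ENDO", "LV_EPI"))
  expect_true(all(vapply(cons, `[[`, logical(1), "closed")))
  # sub-pixel: endo boundary radius close to 9.5 px (between centres)
  endo <- cons[[which(labs == "LV_ENDO")[1]]]
  rr <- sqrt(rowSums(sweep(endo$points, 2, c(30, 30))^2))
  expect_lt(max(abs(rr - mean(rr))), 1.0)
  expect_equal(mean(rr), 9.5, tolerance = 0.1)

  # RV-only mask
  mask2 <- matrix(0L, 60, 60)
  mask2[20:40, 20:40] <- 3L
  cons2 <- masks_to_contours(mask2, p)
  expect_true(all(vapply(cons2, `[[`, character(1), "label") == "RV_ENDO"))

  # all-background
  expect_length(masks_to_contours(matrix(0L, 60, 60), p), 0)
})

test_that("septum points border both LV myocardium and RV cavity", {
  spec <- fx_spec()
  spec$noise_sd <- 0
  p <- fx_planes()[[6]]
  m <- slice_phantom(spec, p)$mask
  cons <- masks_to_contours(m, p)
  labs <- vapply(cons, `[[`, character(1), "label")
  expect_true("SEPTUM" %in% labs)
  near_class <- function(pts, cls) {
    ij <- cbind(round(pts[, 2] / p$spacing[2]) + 1, round(pts[, 1] / p$spacing[1]) + 1)
    vapply(seq_len(nrow(ij)), function(k) {
      any(m[max(1, ij[k, 1] - 2):min(nrow(m), ij[k, 1] + 2),
            max(1, ij[k, 2] - 2):min(ncol(m), ij[k, 2] + 2)] == cls)
    }, logical(1))
  }
  for (cc in cons[labs == "SEPTUM"]) {
    expect_true(mean(near_class(cc$points, 2L)) > 0.95)  # borders LV myocardium
    expect_true(mean(near_class(cc$points, 3L)) > 0.95)  # and RV cavity
  }
})

test_that("mask-derived contours recover analytic contours within a pixel", {
  spec <- fx_spec()
  spec$noise_sd <- 0
  p <- fx_planes()[[7]]
  m <- slice_phantom(spec, p)$mask
  mask_cons <- masks_to_contours(m, p)
  ana_cons <- analytic_contours(spec, p)
  # compare the LV endocardial boundary (Hausdorff within one pixel spacing)
  gm <- function(cons) {
    do.call(rbind, lapply(cons[vapply(cons, `[[`, character(1), "label") == "LV_ENDO"],
                          `[[`, "points"))
  }
  A <- gm(mask_cons); B <- gm(ana_cons)
  d2 <- outer(rowSums(A^2), rep(1, nrow(B))) + outer(rep(1, nrow(A)), rowSums(B^2)) -
    2 * A %*% t(B)
  h <- max(sqrt(pmax(apply(d2, 1, min), 0)), sqrt(pmax(apply(d2, 2, min), 0)))
  expect_lt(h, 1.5 * max(p$spacing))
})

test_that("RV epicardium synthesis offsets by a uniform wall thickness", {
  # circular arc radius 20 -> radius 23 outward
  th <- seq(0, 2 * pi, length.out = 252)[-252]
  circ <- labelled_contour("RV_ENDO", cbind(40 + 20 * cos(th), 40 + 20 * sin(th)),
                           closed = TRUE)
  epi <- synthesize_rv_epi(circ, thickness = 3)
  r <- sqrt(rowSums(sweep(epi$points, 2, c(40, 40))^2))
  expect_lt(max(abs(r - 23)), 0.05)
  # perimeter 2 pi (r + 3)
  per <- sum(sqrt(rowSums(diff(rbind(epi$points, epi$points[1, ]))^2)))
  expect_equal(per, 2 * pi * 23, tolerance = 0.01)
  expect_equal(epi$label, "RV_EPI")

  # open arc: every output point at the prescribed distance from the source
  arc <- labelled_contour("RV_ENDO",
                          cbind(30 + 20 * cos(th[1:60]), 30 + 20 * sin(th[1:60])))
  off <- synthesize_rv_epi(arc, thickness = 3, outward = c(1, 1))
  d <- cinemesh:::.dist_to_polyline2(off$points, arc$points, closed = FALSE)
  inner <- 5:(nrow(off$points) - 5)   # away from the free ends
  expect_lt(max(abs(d[inner] - 3)), 0.05)

  expect_error(synthesize_rv_epi(circ, thickness = -1), "positive")
})
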