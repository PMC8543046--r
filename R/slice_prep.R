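# Slice preparation: SAX/LAX classification by plane orientation, cardiac
# phase selection by LV volume extremum, contour extraction from label masks
# (marching squares at the class interfaces, septum by class adjacency), and
# synthesis of the RV epicardial contour at a uniform wall thickness.

#' Classify slices into a SAX stack and LAX views
#'
#' The largest group of mutually parallel planes (normals within the tolerance)
#' with at least `min_sax` members forms the short-axis stack, ordered along
#' the shared normal; all remaining planes are long-axis views.
#'
#' @param planes list of `slice_plane`s.
#' @param parallel_tol_deg maximum normal angle within the SAX group, degrees.
#' @param min_sax minimum SAX stack size.
#' @return object of class `study_layout`: list with `sax` (ordered), `lax`,
#'   `sax_normal`, and the original indices `sax_idx`, `lax_idx`.
#' @export
classify_slices <- function(planes, parallel_tol_deg = 10, min_sax = 3) {
  if (length(planes) < 1) stop("no planes supplied", call. = FALSE)
  normals <- t(vapply(planes, plane_normal, numeric(3)))
  n <- length(planes)
  cosang <- abs(normals %*% t(normals))
  thr <- cos(parallel_tol_deg * pi / 180)
  group_sizes <- rowSums(cosang >= thr)
  best <- which.max(group_sizes)
  members <- which(cosang[best, ] >= thr)
  if (length(members) < min_sax) {
    ori <- apply(normals, 1, function(x) paste(sprintf("%.3f", x), collapse = ","))
    stop(sprintf("no group of >= %d parallel planes found; normals: %s",
                 min_sax, paste(ori, collapse = " | ")), call. = FALSE)
  }
  axis <- normals[best, ]
  proj <- vapply(members, function(k) sum(planes[[k]]$origin * axis), numeric(1))
  ord <- order(proj)
  sax_idx <- members[ord]
  lax_idx <- setdiff(seq_len(n), members)
  if (length(lax_idx) == 0)
    warning("no LAX view found; at least one LAX and three SAX views are recommended")
  if (length(sax_idx) < 3)
    warning("fewer than three SAX views; results may be unreliable")
  sax <- lapply(planes[sax_idx], function(p) { p$view <- "SAX"; p })
  lax <- lapply(planes[lax_idx], function(p) { p$view <- "LAX"; p })
  structure(list(sax = sax, lax = lax, sax_normal = axis,
                 sax_idx = sax_idx, lax_idx = lax_idx),
            class = "study_layout")
}

#' @export
print.study_layout <- function(x, ...) {
  cat(sprintf("<study_layout: %d SAX + %d LAX>\n", length(x$sax), length(x$lax)))
  invisible(x)
}

#' LV cavity volume from a segmented SAX stack
#'
#' Summed LV-cavity pixel area times the inter-slice gap.
#'
#' @param masks list of integer mask matrices (class 1 = LV cavity).
#' @param spacings list (or single) of length-2 pixel spacings, mm.
#' @param slice_gap inter-slice distance, mm.
#' @param cavity_class mask value of the LV cavity.
#' @return volume in mm^3.
#' @export
lv_volume <- function(masks, spacings, slice_gap, cavity_class = 1L) {
  if (!is.list(masks)) masks <- list(masks)
  if (!is.list(spacings)) spacings <- rep(list(spacings), length(masks))
  if (length(spacings) != length(masks))
    stop("masks and spacings lengths differ", call. = FALSE)
  v <- 0
  for (k in seq_along(masks)) {
    px_area <- prod(spacings[[k]][1:2])
    v <- v + sum(masks[[k]] == cavity_class) * px_area * slice_gap
  }
  v
}

#' Select end-diastolic and end-systolic phases
#'
#' End-diastole is the phase of maximum LV volume, end-systole the minimum;
#' ties resolve to the lowest index.
#'
#' @param volumes numeric vector of per-phase LV volumes.
#' @return list with `ed` and `es` (1-based phase indices).
#' @export
select_phase <- function(volumes) {
  if (length(volumes) < 1) stop("no phases supplied", call. = FALSE)
  list(ed = which.max(volumes), es = which.min(volumes))
}

# ---------------------------------------------------------------------------
# Mask -> contours

# marching squares at a binary interface, sub-pixel, in in-plane mm coords
.mask_isolines <- function(indicator, plane) {
  nr <- nrow(indicator); nc <- ncol(indicator)
  xs <- (seq_len(nc) - 1) * plane$spacing[1]
  ys <- (seq_len(nr) - 1) * plane$spacing[2]
  # contourLines expects z[x, y]: transpose so x = columns direction
  cl <- contourLines(xs, ys, t(indicator), levels = 0.5)
  lapply(cl, function(cv) {
    P <- cbind(cv$x, cv$y)
    closed <- sqrt(sum((P[1, ] - P[nrow(P), ])^2)) < 1e-9
    if (closed) P <- P[-nrow(P), , drop = FALSE]
    list(points = P, closed = closed)
  })
}

.dilate8 <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  out <- m
  for (di in -1:1) for (dj in -1:1) {
    if (di == 0 && dj == 0) next
    si <- max(1, 1 + di):min(nr, nr + di)
    sj <- max(1, 1 + dj):min(nc, nc + dj)
    out[si - di, sj - dj] <- out[si - di, sj - dj] | m[si, sj]
  }
  out
}

# 8-neighbour adjacency of a pixel set to a class
.adjacent_to <- function(mask, class_a, class_b) {
  a <- mask == class_a
  b <- mask == class_b
  nr <- nrow(mask); nc <- ncol(mask)
  near_b <- matrix(FALSE, nr, nc)
  for (di in -1:1) for (dj in -1:1) {
    if (di == 0 && dj == 0) next
    si <- max(1, 1 + di):min(nr, nr + di)
    ti <- si - di
    sj <- max(1, 1 + dj):min(nc, nc + dj)
    tj <- sj - dj
    near_b[ti, tj] <- near_b[ti, tj] | b[si, sj]
  }
  a & near_b
}

#' Extract labelled contours from a segmentation mask
#'
#' Boundaries are traced with sub-pixel marching squares at the class
#' interfaces: the LV endocardium between LV cavity and myocardium, the LV
#' epicardium at the outer myocardial border, and the RV endocardium at the RV
#' cavity border. Epicardial/RV-endocardial boundary points adjacent (within
#' one pixel, 8-neighbourhood) to both the LV myocardium and the RV cavity are
#' relabelled as septum — the shared wall where the LV epicardium meets the RV
#' endocardium.
#'
#' @param mask integer matrix: 0 background, 1 LV cavity, 2 LV myocardium,
#'   3 RV cavity.
#' @param plane the owning `slice_plane`.
#' @param min_points drop fragments shorter than this.
#' @return list of [labelled_contour()]s (possibly empty).
#' @export
masks_to_contours <- function(mask, plane, min_points = 4) {
  if (all(mask == 0)) return(list())
  res <- list()
  emit <- function(curves, label, septum_mask = NULL) {
    for (cv in curves) {
      P <- cv$points
      if (nrow(P) < min_points) next
      if (is.null(septum_mask)) {
        res[[length(res) + 1L]] <<- labelled_contour(label, P, cv$closed,
                                                     slice_id = plane$id)
      } else {
        # split the curve into septal and non-septal runs by pixel adjacency
        ij <- cbind(pmin(pmax(round(P[, 2] / plane$spacing[2]), 0), nrow(mask) - 1) + 1,
                    pmin(pmax(round(P[, 1] / plane$spacing[1]), 0), ncol(mask) - 1) + 1)
        on_sept <- septum_mask[ij]
        for (rn in .mask_runs(on_sept, cv$closed)) {
          if (length(rn) < min_points) next
          res[[length(res) + 1L]] <<- labelled_contour(
            "SEPTUM", P[rn, , drop = FALSE],
            closed = cv$closed && length(rn) == nrow(P), slice_id = plane$id)
        }
        for (rn in .mask_runs(!on_sept, cv$closed)) {
          if (length(rn) < min_points) next
          res[[length(res) + 1L]] <<- labelled_contour(
            label, P[rn, , drop = FALSE],
            closed = cv$closed && length(rn) == nrow(P), slice_id = plane$id)
        }
      }
    }
  }
  # LV endocardium: boundary of the cavity against the myocardium
  if (any(mask == 1L))
    emit(.mask_isolines((mask == 1L) * 1, plane), "LV_ENDO")
  # septum pixels: where LV myocardium touches RV cavity (and vice versa),
  # dilated one pixel so sub-pixel boundary points land on the set
  sept_px <- .dilate8(.adjacent_to(mask, 2L, 3L) | .adjacent_to(mask, 3L, 2L))
  if (any(mask == 2L)) {
    # outer myocardial boundary: trace myocardium+cavity region, drop the part
    # that is the endocardium (interior holes are separate isolines)
    lv_region <- (mask == 1L | mask == 2L) * 1
    curves <- .mask_isolines(lv_region, plane)
    # keep only outer boundaries (enclosing the myocardium): identify by
    # testing whether curve points sit next to myocardium rather than cavity
    emit(curves, "LV_EPI", septum_mask = sept_px)
  }
  if (any(mask == 3L))
    emit(.mask_isolines((mask == 3L) * 1, plane), "RV_ENDO", septum_mask = sept_px)
  res
}

#' Synthesize an RV epicardial contour at uniform wall thickness
#'
#' Offsets the RV endocardial contour outward (away from the LV side) by the
#' wall thickness along the local in-plane normal; offset points that come
#' closer than the thickness to the source polyline (self-intersection of the
#' offset at concavities) are pruned.
#'
#' @param rv_endo a `labelled_contour` with label `RV_ENDO`.
#' @param thickness wall thickness, mm (3 mm default).
#' @param outward optional 2-vector hint for the outward side; default is away
#'   from the contour centroid's concave side.
#' @return a `labelled_contour` labelled `RV_EPI`.
#' @export
synthesize_rv_epi <- function(rv_endo, thickness = 3, outward = NULL) {
  if (thickness <= 0) stop("thickness must be positive", call. = FALSE)
  P <- rv_endo$points
  n <- nrow(P)
  closed <- rv_endo$closed
  # local tangents (central differences; one-sided at open ends)
  nxt <- if (closed) c(2:n, 1) else c(2:n, n)
  prv <- if (closed) c(n, 1:(n - 1)) else c(1, 1:(n - 1))
  tg <- P[nxt, , drop = FALSE] - P[prv, , drop = FALSE]
  len <- sqrt(rowSums(tg^2))
  tg <- tg / pmax(len, 1e-12)
  nrm <- cbind(-tg[, 2], tg[, 1])
  # outward side: for a closed CCW contour the left normal points inward;
  # choose the sign pointing away from the centroid (or the supplied hint)
  ctr <- colMeans(P)
  side <- rowSums(nrm * sweep(P, 2, ctr))
  if (!is.null(outward)) side <- rep(sum(colMeans(nrm) * outward), n)
  sgn <- ifelse(side >= 0, 1, -1)
  if (closed) sgn <- rep(sign(sum(side)), n)  # coherent side for closed loops
  Q <- P + thickness * nrm * sgn
  # prune offset points that fell closer than the thickness to the source
  # polyline (concave self-intersections)
  d <- .dist_to_polyline2(Q, P, closed)
  keep <- d >= thickness - 0.05
  Q <- Q[keep, , drop = FALSE]
  if (nrow(Q) < 3) stop("offset collapsed; contour too small for the thickness",
                        call. = FALSE)
  labelled_contour("RV_EPI", Q, closed = closed && all(keep),
                   slice_id = rv_endo$slice_id)
}

# min distance of each query point to a 2D polyline
.dist_to_polyline2 <- function(Q, P, closed = FALSE) {
  A <- P
  B <- if (closed) P[c(2:nrow(P), 1), , drop = FALSE] else P[-1, , drop = FALSE]
  if (!closed) A <- P[-nrow(P), , drop = FALSE]
  ab <- B - A
  ab2 <- pmax(rowSums(ab^2), 1e-18)
  out <- numeric(nrow(Q))
  for (k in seq_len(nrow(Q))) {
    ap <- sweep(-A, 2, -Q[k, ])  # Q[k] - A
    t <- pmin(pmax((ap[, 1] * ab[, 1] + ap[, 2] * ab[, 2]) / ab2, 0), 1)
    dx <- ap[, 1] - t * ab[, 1]
    dy <- ap[, 2] - t * ab[, 2]
    out[k] <- sqrt(min(dx^2 + dy^2))
  }
  out
}
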