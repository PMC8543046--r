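# Surface reconstruction from aligned sparse contours: initial lofted meshes
# connecting the SAX contour loops (apex initialised from the lowest LAX
# contour point when available), iterative thin-plate-spline deformation
# toward the contours, attractor-based separation of intersecting
# endocardial/epicardial surfaces, and the basal join into one watertight
# biventricular surface.

# assemble the arcs of one slice belonging to a surface into a closed loop
.assemble_loop <- function(arcs) {
  if (length(arcs) == 0) return(NULL)
  if (length(arcs) == 1) {
    return(list(points = arcs[[1]]$points, closed = arcs[[1]]$closed))
  }
  pieces <- lapply(arcs, `[[`, "points")
  used <- rep(FALSE, length(pieces))
  cur <- pieces[[1]]
  used[1] <- TRUE
  while (!all(used)) {
    tail_pt <- cur[nrow(cur), ]
    best <- NULL; best_d <- Inf; best_rev <- FALSE
    for (k in which(!used)) {
      P <- pieces[[k]]
      d1 <- sum((P[1, ] - tail_pt)^2)
      d2 <- sum((P[nrow(P), ] - tail_pt)^2)
      if (d1 < best_d) { best_d <- d1; best <- k; best_rev <- FALSE }
      if (d2 < best_d) { best_d <- d2; best <- k; best_rev <- TRUE }
    }
    P <- pieces[[best]]
    if (best_rev) P <- P[rev(seq_len(nrow(P))), , drop = FALSE]
    cur <- rbind(cur, P)
    used[best] <- TRUE
  }
  list(points = cur, closed = TRUE)
}

#' Initial surface from stacked contour loops
#'
#' Lofts the closed per-slice loops ordered along the stack axis into an
#' open-top surface. The apex vertex is taken from the lowest long-axis
#' contour point when available, otherwise extrapolated half an inter-slice
#' gap below the lowest loop.
#'
#' @param loops list of k x 3 matrices (closed per-slice loops in 3D).
#' @param axis stack axis (unit 3-vector pointing apex -> base).
#' @param lax_points optional LAX contour points of the same surface (apex
#'   initialisation).
#' @param n_theta loft resolution per ring.
#' @param label surface label.
#' @return an edge-manifold `surface_mesh` with one open (basal) boundary.
#' @export
init_surface <- function(loops, axis, lax_points = NULL, n_theta = 40,
                         label = "BIVENTRICULAR") {
  if (length(loops) < 2)
    stop("at least 2 stacked contour loops are required", call. = FALSE)
  axis <- .unit(axis)
  proj <- vapply(loops, function(P) mean(P %*% axis), numeric(1))
  ord <- order(proj)
  loops <- loops[ord]; proj <- proj[ord]
  gap <- median(diff(proj))
  # in-plane basis for ring parameterisation
  ref <- if (abs(axis[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- .unit(ref - sum(ref * axis) * axis)
  e2 <- .cross3(axis, e1)
  rings <- lapply(loops, function(P) {
    Q <- .resample_polyline(P, n = n_theta, closed = TRUE)
    ctr <- colMeans(Q)
    xy <- cbind((Q[, 1] - ctr[1]) * e1[1] + (Q[, 2] - ctr[2]) * e1[2] + (Q[, 3] - ctr[3]) * e1[3],
                (Q[, 1] - ctr[1]) * e2[1] + (Q[, 2] - ctr[2]) * e2[2] + (Q[, 3] - ctr[3]) * e2[3])
    # consistent orientation (CCW in the e1/e2 frame)
    if (.polygon_area2(xy) < 0) {
      Q <- Q[rev(seq_len(nrow(Q))), , drop = FALSE]
      xy <- xy[rev(seq_len(nrow(xy))), , drop = FALSE]
    }
    # consistent start: point of maximal projection on e1 from the centroid
    s <- which.max(xy[, 1])
    idx <- c(s:nrow(Q), seq_len(s - 1))
    Q[idx, , drop = FALSE]
  })
  apex <- NULL
  if (!is.null(lax_points) && nrow(lax_points) > 0) {
    ax_proj <- lax_points %*% axis
    cand <- lax_points[which.min(ax_proj), ]
    if (min(ax_proj) < proj[1]) apex <- as.numeric(cand)
  }
  if (is.null(apex)) {
    apex <- colMeans(rings[[1]]) - 0.5 * gap * axis
  }
  # an intermediate shrink ring eases the apex fan into the first loop
  mid <- sweep(rings[[1]], 2, apex, `-`) * 0.55
  mid <- sweep(mid, 2, apex, `+`)
  m <- .loft_rings(c(list(mid), rings), apex = apex, cap_top = FALSE)
  m$label <- label
  m
}

#' Iterative TPS fitting of a surface to contour points
#'
#' Per iteration: subsample the contour points, find each point's closest
#' location on the current mesh, build an interpolating thin-plate spline from
#' those mesh points to the contour points, warp the whole mesh, and apply one
#' light Laplacian smoothing pass. Stops after `n_iter` iterations or when the
#' mean contour-to-mesh distance changes by less than `tol`.
#'
#' @param mesh initial `surface_mesh`.
#' @param contours3d n x 3 matrix of target contour points.
#' @param n_iter maximum iterations.
#' @param max_controls TPS control budget per iteration.
#' @param lambda smoothing weight per iteration.
#' @param tol residual-change stop, mm.
#' @return the fitted `surface_mesh` with attribute `residual_trace` (mean
#'   contour-to-mesh distance per iteration).
#' @export
fit_surface <- function(mesh, contours3d, n_iter = 10, max_controls = 400,
                        lambda = 0.2, tol = 1e-3) {
  contours3d <- as.matrix(contours3d)
  trace <- numeric(0)
  prev <- Inf
  best <- list(mesh = mesh, residual = Inf)
  for (it in seq_len(n_iter)) {
    sel <- if (nrow(contours3d) > max_controls)
      round(seq(1, nrow(contours3d), length.out = max_controls)) else seq_len(nrow(contours3d))
    P <- contours3d[sel, , drop = FALSE]
    q <- point_to_mesh_distance(P, mesh, details = TRUE)
    res_all <- mean(point_to_mesh_distance(contours3d, mesh))
    trace <- c(trace, res_all)
    if (res_all < best$residual) best <- list(mesh = mesh, residual = res_all)
    if (abs(prev - res_all) < tol) break
    prev <- res_all
    warp <- tps_warp(q$nearest, P)
    V <- tps_apply(warp, mesh$vertices)
    mesh <- surface_mesh(V, mesh$triangles, mesh$label, check = FALSE)
    mesh <- laplacian_smooth(mesh, lambda = lambda, iterations = 1)
  }
  # the smoothing pass can trade a little residual for fairness late in the
  # iteration; the best iterate is returned
  mesh <- best$mesh
  attr(mesh, "residual_trace") <- trace
  mesh
}

# temporarily cap open boundary loops so inside tests work
.capped <- function(mesh) {
  loops <- mesh_boundary_loops(mesh)
  if (length(loops) == 0) return(mesh)
  V <- mesh$vertices
  F <- mesh$triangles
  for (lp in loops) {
    P <- V[lp, , drop = FALSE]
    ctr <- colMeans(P)
    nrm <- svd(sweep(P, 2, ctr))$v[, 3]
    e1 <- .unit(svd(sweep(P, 2, ctr))$v[, 1])
    e2 <- .cross3(nrm, e1)
    xy <- cbind(sweep(P, 2, ctr) %*% e1, sweep(P, 2, ctr) %*% e2)
    tri <- .ear_clip(xy)
    F <- rbind(F, matrix(lp[tri], ncol = 3))
  }
  surface_mesh(V, F, mesh$label, check = FALSE)
}

#' Resolve endocardial/epicardial surface intersections
#'
#' Epicardial vertices lying inside the endocardial surface become attractor
#' targets pushing the two surfaces apart by a clearance margin (and vice
#' versa), realised as TPS warps anchored on the non-offending vertices. If
#' offending patches remain after `passes` attractor passes, they are embedded
#' directly into the partner surface at the clearance distance (the residual
#' endocardial patch effectively becomes epicardium), followed by Laplacian
#' smoothing. The returned meshes have no crossing triangle pairs.
#'
#' @param endo,epi `surface_mesh`es (open basal boundary allowed).
#' @param clearance separation margin, mm.
#' @param passes attractor passes before the direct embedding rule.
#' @return list with `endo`, `epi`, `crossings` (final count, 0 on success).
#' @export
resolve_intersections <- function(endo, epi, clearance = 0.5, passes = 2) {
  offenders <- function(endo, epi) {
    epi_c <- .capped(epi)
    bvh_epi <- mesh_bvh(epi_c)
    out_endo <- which(!mesh_inside(endo$vertices, bvh_epi))
    endo_c <- .capped(endo)
    bvh_endo <- mesh_bvh(endo_c)
    in_epi <- which(mesh_inside(epi$vertices, bvh_endo))
    list(endo = out_endo, epi = in_epi, bvh_epi = bvh_epi, bvh_endo = bvh_endo)
  }
  # exclude basal-boundary vertices (the open rim legitimately meets the lid)
  rim_endo <- unique(as.vector(mesh_boundary_edges(endo)))
  rim_epi <- unique(as.vector(mesh_boundary_edges(epi)))
  pull_inside <- function(mesh, ids, bvh_partner, inward_ctr, sign) {
    # sign = -1: pull inside the partner; +1: push outside
    q <- point_to_mesh_distance(mesh$vertices[ids, , drop = FALSE], bvh_partner,
                                details = TRUE)
    dir <- q$nearest - matrix(inward_ctr, length(ids), 3, byrow = TRUE)
    dir <- dir / pmax(sqrt(rowSums(dir^2)), 1e-9)
    q$nearest + sign * clearance * dir
  }
  ob <- offenders(endo, epi)
  if (length(ob$endo) == 0 && length(ob$epi) == 0)
    return(list(endo = endo, epi = epi, crossings = mesh_crossings(endo, epi)))
  for (p in seq_len(passes)) {
    ob <- offenders(endo, epi)
    off_e <- setdiff(ob$endo, rim_endo)
    off_p <- setdiff(ob$epi, rim_epi)
    if (length(off_e) == 0 && length(off_p) == 0) break
    ctr <- colMeans(endo$vertices)
    if (length(off_e) > 0) {
      targets <- pull_inside(endo, off_e, ob$bvh_epi, ctr, -1)
      anchors <- setdiff(round(seq(1, nrow(endo$vertices), length.out = 60)), off_e)
      warp <- tps_warp(rbind(endo$vertices[off_e, , drop = FALSE],
                             endo$vertices[anchors, , drop = FALSE]),
                       rbind(targets, endo$vertices[anchors, , drop = FALSE]))
      endo <- surface_mesh(tps_apply(warp, endo$vertices), endo$triangles,
                           endo$label, check = FALSE)
    }
    if (length(off_p) > 0) {
      targets <- pull_inside(epi, off_p, ob$bvh_endo, ctr, +1)
      anchors <- setdiff(round(seq(1, nrow(epi$vertices), length.out = 60)), off_p)
      warp <- tps_warp(rbind(epi$vertices[off_p, , drop = FALSE],
                             epi$vertices[anchors, , drop = FALSE]),
                       rbind(targets, epi$vertices[anchors, , drop = FALSE]))
      epi <- surface_mesh(tps_apply(warp, epi$vertices), epi$triangles,
                          epi$label, check = FALSE)
    }
  }
  # direct embedding of whatever still offends, then smoothing
  for (round in 1:5) {
    ob <- offenders(endo, epi)
    off_e <- setdiff(ob$endo, rim_endo)
    off_p <- setdiff(ob$epi, rim_epi)
    if (length(off_e) == 0 && length(off_p) == 0 &&
        mesh_crossings(endo, epi) == 0) break
    ctr <- colMeans(endo$vertices)
    if (length(off_e) > 0) {
      V <- endo$vertices
      V[off_e, ] <- pull_inside(endo, off_e, ob$bvh_epi, ctr, -1)
      endo <- laplacian_smooth(surface_mesh(V, endo$triangles, endo$label, check = FALSE),
                               lambda = 0.3, iterations = 1)
    }
    if (length(off_p) > 0) {
      V <- epi$vertices
      V[off_p, ] <- pull_inside(epi, off_p, ob$bvh_endo, ctr, +1)
      epi <- laplacian_smooth(surface_mesh(V, epi$triangles, epi$label, check = FALSE),
                              lambda = 0.3, iterations = 1)
    }
    clearance <- clearance * 1.3
  }
  list(endo = endo, epi = epi, crossings = mesh_crossings(endo, epi))
}

#' Join the three surfaces at the basal plane
#'
#' Trims the LV endocardial, RV endocardial and epicardial surfaces to the
#' basal plane (the plane of the most basal SAX contour) and stitches the three
#' boundary loops with a planar annulus-with-two-holes triangulation, yielding
#' one watertight biventricular surface enclosing the myocardial wall.
#'
#' @param lv_endo,rv_endo,epi `surface_mesh`es with open basal boundaries
#'   (`rv_endo` may be NULL for LV-only geometries).
#' @param basal_point a point on the basal plane.
#' @param axis basal plane normal (apex -> base).
#' @return a watertight `surface_mesh` labelled `BIVENTRICULAR`.
#' @export
join_at_base <- function(lv_endo, rv_endo, epi, basal_point, axis) {
  axis <- .unit(axis)
  clip_or_keep <- function(m) {
    d <- as.numeric(m$vertices %*% axis) - sum(axis * basal_point)
    if (any(d > 1e-6)) mesh_clip_plane(m, basal_point, axis) else m
  }
  # orient every part coherently with the enclosed wall: epicardium outward,
  # endocardial cups inward (their outward is into the solid)
  orient_part <- function(m, outward) {
    capped <- .capped(m)
    V <- capped$vertices; F <- capped$triangles
    a <- V[F[, 1], , drop = FALSE]; b <- V[F[, 2], , drop = FALSE]
    cc <- V[F[, 3], , drop = FALSE]
    svol <- sum(a[, 1] * (b[, 2] * cc[, 3] - b[, 3] * cc[, 2]) -
                  a[, 2] * (b[, 1] * cc[, 3] - b[, 3] * cc[, 1]) +
                  a[, 3] * (b[, 1] * cc[, 2] - b[, 2] * cc[, 1]))
    flip <- if (outward) svol < 0 else svol > 0
    if (flip) m$triangles <- m$triangles[, c(1, 3, 2), drop = FALSE]
    m
  }
  parts <- list(epi = clip_or_keep(orient_part(epi, TRUE)),
                lv = clip_or_keep(orient_part(lv_endo, FALSE)))
  if (!is.null(rv_endo)) parts$rv <- clip_or_keep(orient_part(rv_endo, FALSE))
  loops <- lapply(parts, function(m) {
    lp <- mesh_boundary_loops(m)
    if (length(lp) != 1)
      stop(sprintf("expected one basal boundary loop, found %d", length(lp)),
           call. = FALSE)
    lp[[1]]
  })
  # merge vertex arrays
  offs <- cumsum(c(0, vapply(parts, function(m) nrow(m$vertices), 1)))
  V <- do.call(rbind, lapply(parts, `[[`, "vertices"))
  F <- do.call(rbind, mapply(function(m, o) m$triangles + o, parts,
                             offs[seq_along(parts)], SIMPLIFY = FALSE))
  # lid: outer loop = epi, holes = endo loops, in the basal plane frame
  e1 <- .unit(if (abs(axis[1]) < 0.9) .cross3(axis, c(1, 0, 0)) else .cross3(axis, c(0, 1, 0)))
  e2 <- .cross3(axis, e1)
  to2d <- function(ids, off) {
    P <- V[ids + off, , drop = FALSE]
    cbind(P %*% e1, P %*% e2)
  }
  outer2 <- to2d(loops$epi, offs[1])
  holes2 <- list(to2d(loops$lv, offs[2]))
  hole_ids <- list(loops$lv + offs[2])
  if (!is.null(parts$rv)) {
    holes2[[2]] <- to2d(loops$rv, offs[3])
    hole_ids[[2]] <- loops$rv + offs[3]
  }
  tri2 <- .triangulate_with_holes(outer2, holes2)
  if (sum(.cross3(e1, e2) * axis) < 0) tri2 <- tri2[, c(1, 3, 2), drop = FALSE]
  idmap <- c(loops$epi + offs[1], unlist(hole_ids))
  lid <- matrix(idmap[tri2], ncol = 3)
  # a lid diagonal can coincide with an interior surface edge of a wiggly rim,
  # giving a non-manifold (multiplicity-4) edge; flip such diagonals away
  ekey <- function(a, b) paste(pmin(a, b), pmax(a, b))
  surf_keys <- unique(ekey(c(F[, 1], F[, 2], F[, 3]), c(F[, 2], F[, 3], F[, 1])))
  for (guard in seq_len(50)) {
    lk <- cbind(ekey(lid[, 1], lid[, 2]), ekey(lid[, 2], lid[, 3]),
                ekey(lid[, 3], lid[, 1]))
    dupcnt <- table(as.vector(lk))
    offending <- intersect(names(dupcnt)[dupcnt == 2], surf_keys)
    if (length(offending) == 0) break
    key <- offending[1]
    hit <- which(lk[, 1] == key | lk[, 2] == key | lk[, 3] == key)
    if (length(hit) != 2) break
    ab <- as.integer(strsplit(key, " ")[[1]])
    others <- vapply(hit, function(t) as.integer(setdiff(lid[t, ], ab))[1], integer(1))
    lid[hit[1], ] <- c(ab[1], others[2], others[1])
    lid[hit[2], ] <- c(others[2], ab[2], others[1])
  }
  F <- rbind(F, lid)
  mesh <- surface_mesh(V, F, "BIVENTRICULAR", check = FALSE)
  if (!mesh_is_watertight(mesh))
    stop("basal join failed to produce a watertight surface", call. = FALSE)
  mesh
}

#' Reconstruct the biventricular surfaces from aligned contours
#'
#' Full reconstruction: per-slice loop assembly from the (re-posed) contours,
#' initial lofts, iterative TPS fitting, endo/epi intersection resolution and
#' the basal join.
#'
#' @param planes list of `slice_plane`s (original poses).
#' @param contours per-slice lists of [labelled_contour()]s.
#' @param thetas per-slice `rigid_params` (NULL = as given).
#' @param n_theta loft resolution.
#' @param n_iter TPS fitting iterations.
#' @param septum_to which surface the septum contour feeds (`"RV_ENDO"`).
#' @return list with `lv_endo`, `rv_endo`, `epi`, `biventricular`,
#'   `basal_point`, `axis`, `residuals` (per-surface fitting traces).
#' @export
reconstruct_surfaces <- function(planes, contours, thetas = NULL, n_theta = 40,
                                 n_iter = 10, septum_to = "RV_ENDO") {
  n <- length(planes)
  if (is.null(thetas)) thetas <- replicate(n, rigid_params(), simplify = FALSE)
  pt <- mapply(apply_rigid, planes, thetas, SIMPLIFY = FALSE)
  layout <- classify_slices(planes)
  axis <- layout$sax_normal
  sources <- list(LV_ENDO = "LV_ENDO",
                  RV_ENDO = c("RV_ENDO", "SEPTUM"),
                  EPI = c("LV_EPI", "RV_EPI"))
  if (septum_to == "EPI") sources <- list(LV_ENDO = "LV_ENDO", RV_ENDO = "RV_ENDO",
                                          EPI = c("LV_EPI", "RV_EPI", "SEPTUM"))
  # collect per-surface loops (SAX) and scattered targets (all slices)
  loops <- list(); targets <- list(); lax_pts <- list()
  for (s in names(sources)) { loops[[s]] <- list(); targets[[s]] <- list(); lax_pts[[s]] <- list() }
  basal_proj <- -Inf; basal_point <- NULL
  for (k in seq_len(n)) {
    cons <- contours[[k]]
    if (length(cons) == 0) next
    labs <- vapply(cons, `[[`, character(1), "label")
    is_sax <- k %in% layout$sax_idx
    for (s in names(sources)) {
      sel <- which(labs %in% sources[[s]])
      if (length(sel) == 0) next
      arcs <- lapply(cons[sel], function(cc)
        list(points = contour_to_3d(cc, pt[[k]]), closed = cc$closed))
      pts <- do.call(rbind, lapply(arcs, `[[`, "points"))
      targets[[s]][[length(targets[[s]]) + 1L]] <- pts
      if (is_sax) {
        loop <- .assemble_loop(arcs)
        if (!is.null(loop) && nrow(loop$points) >= 8)
          loops[[s]][[length(loops[[s]]) + 1L]] <- loop$points
        pr <- mean(pts %*% axis)
        if (pr > basal_proj) { basal_proj <- pr; basal_point <- colMeans(pts) }
      } else {
        lax_pts[[s]][[length(lax_pts[[s]]) + 1L]] <- pts
      }
    }
  }
  # orient the axis apex -> base using the LV loop area trend
  lv_loops <- loops$LV_ENDO
  if (length(lv_loops) >= 2) {
    areas <- vapply(lv_loops, function(P) {
      ctr <- colMeans(P)
      sum(.tri_areas(rbind(ctr, P),
                     cbind(1, 1 + seq_len(nrow(P)), 1 + c(2:nrow(P), 1))))
    }, numeric(1))
    prj <- vapply(lv_loops, function(P) mean(P %*% axis), numeric(1))
    if (cor(areas, prj) < 0) {
      axis <- -axis
      basal_proj <- -Inf
      for (s in names(sources)) for (P in loops[[s]]) {
        pr <- mean(P %*% axis)
        if (pr > basal_proj) { basal_proj <- pr; basal_point <- colMeans(P) }
      }
    }
  }
  fit_one <- function(sname, label) {
    lp <- loops[[sname]]
    if (length(lp) < 2) return(NULL)
    lax <- if (length(lax_pts[[sname]])) do.call(rbind, lax_pts[[sname]]) else NULL
    m <- init_surface(lp, axis, lax_points = lax, n_theta = n_theta, label = label)
    tg <- do.call(rbind, targets[[sname]])
    fit_surface(m, tg, n_iter = n_iter)
  }
  lv <- fit_one("LV_ENDO", "LV_ENDO")
  rv <- fit_one("RV_ENDO", "RV_ENDO")
  ep <- fit_one("EPI", "EPI")
  if (is.null(lv) || is.null(ep))
    stop("not enough stacked contours to reconstruct the LV and epicardium",
         call. = FALSE)
  residuals <- list(lv_endo = attr(lv, "residual_trace"),
                    rv_endo = attr(rv, "residual_trace"),
                    epi = attr(ep, "residual_trace"))
  r1 <- resolve_intersections(lv, ep)
  lv <- r1$endo; ep <- r1$epi
  if (!is.null(rv)) {
    r2 <- resolve_intersections(rv, ep)
    rv <- r2$endo; ep <- r2$epi
  }
  bv <- join_at_base(lv, rv, ep, basal_point, axis)
  list(lv_endo = lv, rv_endo = rv, epi = ep, biventricular = bv,
       basal_point = basal_point, axis = axis, residuals = residuals)
}
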