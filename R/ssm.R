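# Statistical shape model: a PCA model over corresponded biventricular
# surface vertices. A synthetic model is built from a seeded population of
# phantom variants; fitting alternates nearest-point correspondence, a
# closed-form rigid update and a per-mode ridge-regularised linear solve for
# the PCA coefficients. After stage C the fitted model is discarded: only the
# re-posed slices move downstream.

#' Construct a shape model
#'
#' @param mean_vertices V x 3 matrix, mm.
#' @param modes k x 3V matrix with orthonormal rows (vertex coordinates
#'   flattened column-major: all x, all y, all z).
#' @param variances per-mode variances, non-increasing.
#' @param triangles m x 3 triangle indices (fixed topology).
#' @param vertex_labels per-vertex surface label (`LV_ENDO`, `RV_ENDO`, `EPI`),
#'   or NULL.
#' @return object of class `shape_model`.
#' @export
shape_model <- function(mean_vertices, modes, variances, triangles,
                        vertex_labels = NULL) {
  mean_vertices <- as.matrix(mean_vertices)
  modes <- as.matrix(modes)
  variances <- as.numeric(variances)
  stopifnot(ncol(mean_vertices) == 3,
            ncol(modes) == 3 * nrow(mean_vertices),
            nrow(modes) == length(variances))
  if (any(diff(variances) > 1e-9))
    stop("variances must be non-increasing", call. = FALSE)
  if (any(variances < 0)) stop("variances must be >= 0", call. = FALSE)
  G <- modes %*% t(modes)
  if (max(abs(G - diag(nrow(modes)))) > 1e-6)
    stop("mode vectors must be orthonormal (within 1e-6)", call. = FALSE)
  structure(list(mean_vertices = unname(mean_vertices), modes = unname(modes),
                 variances = variances,
                 triangles = matrix(as.integer(as.matrix(triangles)), ncol = 3),
                 vertex_labels = vertex_labels),
            class = "shape_model")
}

#' @export
print.shape_model <- function(x, ...) {
  cat(sprintf("<shape_model: %d vertices, %d modes; first mode %.1f%% of variance>\n",
              nrow(x$mean_vertices), length(x$variances),
              100 * x$variances[1] / sum(x$variances)))
  invisible(x)
}

#' Cumulative variance fraction per mode count
#' @param model a [shape_model()].
#' @return numeric vector, `cumsum(variances) / total`.
#' @export
ssm_cumulative_variance <- function(model) {
  cumsum(model$variances) / sum(model$variances)
}

#' Instantiate a shape-model surface
#'
#' `instance = mean + sum_k b_k mode_k`, optionally posed by a rigid map.
#'
#' @param model a [shape_model()].
#' @param b coefficient vector (padded with zeros).
#' @param pose optional list with rotation `R` (3 x 3) and offset `t`.
#' @return a `surface_mesh` (label `BIVENTRICULAR`).
#' @export
ssm_instance <- function(model, b = numeric(0), pose = NULL) {
  V <- nrow(model$mean_vertices)
  x <- as.vector(model$mean_vertices)
  if (length(b) > 0) {
    k <- min(length(b), nrow(model$modes))
    x <- x + as.vector(t(model$modes[seq_len(k), , drop = FALSE]) %*% b[seq_len(k)])
  }
  verts <- matrix(x, V, 3)
  if (!is.null(pose)) verts <- verts %*% t(pose$R) + matrix(pose$t, V, 3, byrow = TRUE)
  surface_mesh(verts, model$triangles, check = FALSE)
}

# ---------------------------------------------------------------------------
# Synthetic population sampling with correspondence by construction

# corresponded vertex sampling of one phantom's three surfaces
.ssm_sample_vertices <- function(spec, n_rings = 16, n_theta = 32, rv_rings = 12) {
  a_endo <- spec$lv_semi_axes
  a_epi <- spec$lv_semi_axes + spec$lv_wall
  theta <- seq(0, 2 * pi, length.out = n_theta + 1)[-(n_theta + 1)]
  ring_z <- function(z_lo, z_hi, n) z_lo + (z_hi - z_lo) * (seq_len(n) - 0.5) / n
  # LV endocardium
  zs <- ring_z(-a_endo[3] + 0.02 * a_endo[3], min(spec$base_height, a_endo[3] * 0.98), n_rings)
  lv <- do.call(rbind, lapply(zs, function(z) {
    w <- sqrt(max(1 - (z / a_endo[3])^2, 1e-8))
    cbind(a_endo[1] * w * cos(theta), a_endo[2] * w * sin(theta), z)
  }))
  lv <- rbind(c(0, 0, -a_endo[3]), lv)
  # epicardial union boundary
  zs_e <- ring_z(-a_epi[3] + 0.02 * a_epi[3], min(spec$base_height, a_epi[3] * 0.98), n_rings)
  ep <- do.call(rbind, lapply(zs_e, function(z) {
    r <- .union_radius(theta, z, spec)
    cbind(r * cos(theta), r * sin(theta), z)
  }))
  ep <- rbind(c(0, 0, -a_epi[3]), ep)
  # RV cavity boundary (two-arc crescent loops)
  rv <- NULL
  if (.has_rv(spec)) {
    rng <- .rv_cavity_zrange(spec)
    z0 <- rng[1]; z1 <- rng[2]
    zs_r <- ring_z(z0 + 0.3, z1 - 0.3, rv_rings)
    rv <- do.call(rbind, lapply(zs_r, function(z) {
      loop <- .rv_section_loop(z, spec)
      P <- .resample_polyline(loop, n = n_theta, closed = TRUE)
      cbind(P, z)
    }))
  }
  list(lv = lv, epi = ep, rv = rv)
}


# z-range over which the crescent cavity exists, refined by bisection so it
# varies smoothly with the shape parameters
.rv_cavity_zrange <- function(spec, n_phi = 128) {
  zc <- spec$rv_offset[3]; cz <- spec$rv_semi_axes[3]
  has <- function(z) !is.null(.rv_section_loop(z, spec, n_phi))
  z_probe <- seq(zc - cz + 0.25, min(spec$base_height, zc + cz - 0.25), by = 0.5)
  ok <- vapply(z_probe, has, logical(1))
  if (!any(ok)) stop("phantom has no RV cavity", call. = FALSE)
  lo <- min(z_probe[ok]); hi <- max(z_probe[ok])
  bz <- function(a, b) {   # bisect the existence boundary
    for (it in 1:30) {
      mid <- (a + b) / 2
      if (has(mid)) b <- mid else a <- mid
    }
    b
  }
  z0 <- if (ok[1]) lo else bz(lo - 0.5, lo)
  zt <- min(spec$base_height, zc + cz - 0.25)
  z1 <- if (ok[length(ok)]) hi else -bz(-(hi + 0.5), -hi)
  # the upper end: either truncated at the base or closes below it
  if (!ok[length(ok)]) {
    a <- hi; b <- hi + 0.5
    for (it in 1:30) {
      mid <- (a + b) / 2
      if (has(mid)) a <- mid else b <- mid
    }
    z1 <- a
  } else z1 <- hi
  c(z0, z1)
}

# fixed loft topology matching .ssm_sample_vertices
.ssm_topology <- function(n_rings, n_theta, rv_rings, has_rv) {
  ring_tris <- function(offset, n_r) {
    F <- list()
    j <- seq_len(n_theta); j2 <- c(2:n_theta, 1)
    for (r in seq_len(n_r - 1)) {
      o1 <- offset + (r - 1) * n_theta; o2 <- offset + r * n_theta
      F[[length(F) + 1L]] <- cbind(o1 + j, o1 + j2, o2 + j)
      F[[length(F) + 1L]] <- cbind(o1 + j2, o2 + j2, o2 + j)
    }
    do.call(rbind, F)
  }
  apex_fan <- function(apex, offset) {
    j <- seq_len(n_theta); j2 <- c(2:n_theta, 1)
    cbind(apex, offset + j2, offset + j)
  }
  nv_lv <- 1 + n_rings * n_theta
  F <- rbind(apex_fan(1L, 1L), ring_tris(1L, n_rings))
  off <- nv_lv
  F <- rbind(F, apex_fan(off + 1L, off + 1L), ring_tris(off + 1L, n_rings))
  labels <- c(rep("LV_ENDO", nv_lv), rep("EPI", nv_lv))
  if (has_rv) {
    off2 <- 2L * nv_lv
    F <- rbind(F, ring_tris(off2, rv_rings))
    labels <- c(labels, rep("RV_ENDO", rv_rings * n_theta))
  }
  list(triangles = F, labels = labels)
}

#' Build a synthetic PCA shape model from a seeded phantom population
#'
#' Generates `n_samples` phantom variants by perturbing the shape parameters
#' (LV semi-axes, wall thickness, RV offset and semi-axes) with the given
#' relative/absolute SDs, samples each variant's three surfaces with the same
#' parameterisation (correspondence by construction), and runs PCA on the
#' flattened vertex coordinates.
#'
#' @param spec base [phantom_spec()].
#' @param n_samples population size (must exceed `n_modes`).
#' @param n_modes number of retained modes.
#' @param seed seed for the population draws.
#' @param rel_sd relative SD of the LV/RV semi-axis scalings.
#' @param wall_sd SD of the LV wall thickness, mm.
#' @param offset_sd SD of the RV lateral offset, mm.
#' @param n_rings,n_theta,rv_rings sampling density per surface.
#' @return a [shape_model()] with attribute `cumulative_variance`.
#' @export
make_synthetic_ssm <- function(spec, n_samples = 200, n_modes = 100, seed = 1L,
                               rel_sd = 0.06, wall_sd = 0.8, offset_sd = 2,
                               n_rings = 16, n_theta = 32, rv_rings = 12) {
  if (n_samples < n_modes + 1)
    n_modes <- n_samples - 1
  if (n_samples < 2) stop("population too small", call. = FALSE)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  has_rv <- .has_rv(spec)
  draws <- vector("list", n_samples)
  k <- 0L
  while (k < n_samples) {
    cand <- try(phantom_spec(
      lv_semi_axes = spec$lv_semi_axes * (1 + rnorm(3, 0, rel_sd)),
      lv_wall = max(2, spec$lv_wall + rnorm(1, 0, wall_sd)),
      rv_offset = spec$rv_offset + c(rnorm(1, 0, offset_sd), 0, rnorm(1, 0, offset_sd)),
      rv_semi_axes = if (has_rv) spec$rv_semi_axes * (1 + rnorm(3, 0, rel_sd)) else NULL,
      rv_wall = spec$rv_wall, base_height = spec$base_height,
      intensity = spec$intensity, noise_sd = spec$noise_sd), silent = TRUE)
    if (inherits(cand, "try-error")) next
    k <- k + 1L
    draws[[k]] <- cand
  }
  if (!is.null(old)) assign(".Random.seed", old, globalenv())
  X <- t(vapply(draws, function(s) {
    sv <- .ssm_sample_vertices(s, n_rings, n_theta, rv_rings)
    as.vector(rbind(sv$lv, sv$epi, sv$rv))
  }, numeric((2 * (1 + n_rings * n_theta) + if (has_rv) rv_rings * n_theta else 0) * 3)))
  if (max(apply(X, 2, sd)) < 1e-9)
    stop("degenerate population: zero shape variance", call. = FALSE)
  pc <- prcomp(X, center = TRUE, scale. = FALSE)
  k_keep <- min(n_modes, length(pc$sdev), sum(pc$sdev > 1e-12))
  topo <- .ssm_topology(n_rings, n_theta, rv_rings, has_rv)
  model <- shape_model(
    mean_vertices = matrix(pc$center, ncol = 3),
    modes = t(pc$rotation[, seq_len(k_keep), drop = FALSE]),
    variances = pc$sdev[seq_len(k_keep)]^2,
    triangles = topo$triangles,
    vertex_labels = topo$labels)
  attr(model, "cumulative_variance") <- cumsum(pc$sdev^2) / sum(pc$sdev^2)
  model
}

# ---------------------------------------------------------------------------
# Fitting the model to sparse contours

.model_label_map <- c(LV_ENDO = "LV_ENDO", RV_ENDO = "RV_ENDO", SEPTUM = "RV_ENDO",
                      LV_EPI = "EPI", RV_EPI = "EPI", EPI = "EPI")

# label-pure triangle subsets of a model/mesh given per-vertex labels
.label_submeshes <- function(verts, tris, vlabels) {
  out <- list()
  for (L in unique(vlabels)) {
    keep <- which(matrix(vlabels[tris], ncol = 3)[, 1] == L &
                    matrix(vlabels[tris], ncol = 3)[, 2] == L &
                    matrix(vlabels[tris], ncol = 3)[, 3] == L)
    if (length(keep) == 0) next
    out[[L]] <- list(triangles = tris[keep, , drop = FALSE])
  }
  out
}

#' Fit a shape model to labelled sparse 3D contour points
#'
#' Alternates (1) nearest-point correspondences from each contour point to the
#' label-matched posed model surface, (2) a closed-form rigid pose update
#' (least-squares rotation + translation), and (3) a linear solve for the PCA
#' coefficients with per-mode ridge `lambda_k = sigma_noise^2 / variance_k`
#' and a `|b_k| <= 3 sqrt(variance_k)` clamp, until the mean residual changes
#' by less than `tol` or `max_iter` rounds.
#'
#' @param model a [shape_model()].
#' @param points n x 3 matrix of contour points in patient space.
#' @param labels per-point anatomical labels (mapped onto the model's surface
#'   labels; septum points seek the RV endocardial surface). NULL = nearest
#'   surface overall.
#' @param max_modes number of modes used (default 100, as many as available).
#' @param sigma_noise contour noise SD for the ridge, mm.
#' @param max_iter,tol alternation controls.
#' @return object of class `ssm_fit`: `b`, `pose` (list `R`, `t`), `surface`
#'   (posed fitted mesh), `residual` (mean point-to-surface distance, mm),
#'   `per_label_residual`, `converged`, `n_iter`.
#' @export
fit_ssm <- function(model, points, labels = NULL, max_modes = 100,
                    sigma_noise = 1, max_iter = 50, tol = 1e-3) {
  points <- as.matrix(points)
  if (nrow(points) < 50)
    stop("too few contour points to constrain the model (need >= 50)", call. = FALSE)
  if (!is.null(labels)) {
    mlab <- .model_label_map[labels]
    if (length(unique(mlab[!is.na(mlab)])) < 2)
      stop("contour points must span at least 2 surface labels", call. = FALSE)
  } else mlab <- rep(NA_character_, nrow(points))
  k <- min(max_modes, nrow(model$modes))
  D <- t(model$modes[seq_len(k), , drop = FALSE])   # 3V x k
  vars <- model$variances[seq_len(k)]
  Vn <- nrow(model$mean_vertices)
  b <- numeric(k)
  R <- diag(3)
  tt <- colMeans(points) - colMeans(model$mean_vertices)
  residual <- Inf
  converged <- FALSE
  vlab <- model$vertex_labels
  res_trace <- numeric(0)
  best <- list(b = b, R = R, t = tt, residual = Inf)
  for (iter in seq_len(max_iter)) {
    verts <- matrix(as.vector(model$mean_vertices) + D %*% b, Vn, 3)
    world <- verts %*% t(R) + matrix(tt, Vn, 3, byrow = TRUE)
    # correspondences per label subset (nearest point on the label-matched
    # surface; the closest corner of the hit triangle carries the mode values)
    near <- matrix(0, nrow(points), 3)
    near_tri <- integer(nrow(points))
    dists <- numeric(nrow(points))
    assign_block <- (function() {
      function(sel, tris) {
        sm <- surface_mesh(world, tris, check = FALSE)
        q <- point_to_mesh_distance(points[sel, , drop = FALSE], sm, details = TRUE)
        near[sel, ] <<- q$nearest
        corners <- tris[q$triangle, , drop = FALSE]
        d2 <- vapply(1:3, function(cn)
          rowSums((world[corners[, cn], , drop = FALSE] - q$nearest)^2), numeric(length(sel)))
        pick <- max.col(-matrix(d2, ncol = 3))
        near_tri[sel] <<- corners[cbind(seq_along(sel), pick)]
        dists[sel] <<- q$distance
      }
    })()
    subs <- if (is.null(vlab)) list(ALL = list(triangles = model$triangles))
            else .label_submeshes(world, model$triangles, vlab)
    for (L in names(subs)) {
      sel <- if (L == "ALL") seq_len(nrow(points))
             else which(!is.na(mlab) & mlab == L)
      if (length(sel) == 0) next
      assign_block(sel, subs[[L]]$triangles)
    }
    unlab <- which(is.na(mlab))
    if (length(unlab) > 0 && !is.null(vlab)) {
      assign_block(unlab, model$triangles)
    }
    new_res <- mean(dists)
    # rigid update: model-frame correspondences -> data points
    m <- sweep(near, 2, tt) %*% R    # back to model frame
    mc <- colMeans(m); pc <- colMeans(points)
    H <- t(sweep(m, 2, mc)) %*% sweep(points, 2, pc)
    sv <- svd(H)
    Rn <- sv$v %*% diag(c(1, 1, det(sv$v %*% t(sv$u)))) %*% t(sv$u)
    tn <- pc - as.numeric(Rn %*% mc)
    R <- Rn; tt <- tn
    # coefficient update: the required surface displacement at each contact
    # point (data minus nearest surface point, rotated into the model frame)
    # is attributed to the nearest vertex and solved for with per-mode ridge
    delta <- (points - near) %*% R
    vi <- near_tri
    rows <- c(vi, Vn + vi, 2L * Vn + vi)
    A <- D[rows, , drop = FALSE]
    rhs <- c(delta[, 1], delta[, 2], delta[, 3]) + as.numeric(A %*% b)
    AtA <- crossprod(A) + diag(sigma_noise^2 / pmax(vars, 1e-12), k)
    b <- as.numeric(solve(AtA, crossprod(A, rhs)))
    b <- pmin(pmax(b, -3 * sqrt(vars)), 3 * sqrt(vars))
    res_trace <- c(res_trace, new_res)
    if (new_res < best$residual) best <- list(b = b, R = R, t = tt, residual = new_res)
    if (is.finite(residual) && abs(residual - new_res) < tol) {
      residual <- new_res
      converged <- TRUE
      break
    }
    residual <- new_res
  }
  # keep the best iterate (guards against a rare worsening step)
  b <- best$b; R <- best$R; tt <- best$t; residual <- best$residual
  if (!converged)
    warning("shape-model fit did not converge; returning the best iterate")
  verts <- matrix(as.vector(model$mean_vertices) + D %*% b, Vn, 3)
  world <- verts %*% t(R) + matrix(tt, Vn, 3, byrow = TRUE)
  surf <- surface_mesh(world, model$triangles, check = FALSE)
  per_label <- NULL
  if (!is.null(labels)) {
    per_label <- tapply(dists, labels, mean)
  }
  structure(list(b = b, pose = list(R = R, t = tt), surface = surf,
                 residual = residual, per_label_residual = per_label,
                 residual_trace = cummin(res_trace),
                 converged = converged, n_iter = iter,
                 vertex_labels = model$vertex_labels),
            class = "ssm_fit")
}

#' @export
print.ssm_fit <- function(x, ...) {
  cat(sprintf("<ssm_fit: %d modes, residual %.3f mm, %s after %d rounds>\n",
              length(x$b), x$residual,
              if (x$converged) "converged" else "not converged", x$n_iter))
  invisible(x)
}

#' Reproject a fitted shape model onto a slice
#'
#' Cross-sections of the fitted surface with the slice plane, one contour per
#' surface component.
#'
#' @param fit an [fit_ssm()] result.
#' @param plane a `slice_plane`.
#' @return list of [labelled_contour()]s (labels `LV_ENDO`, `RV_ENDO`, `EPI`);
#'   empty when the plane misses the surface.
#' @export
reproject_model <- function(fit, plane) {
  vlab <- fit$vertex_labels
  out <- list()
  subs <- if (is.null(vlab)) list(EPI = list(triangles = fit$surface$triangles))
          else .label_submeshes(fit$surface$vertices, fit$surface$triangles, vlab)
  for (L in names(subs)) {
    sm <- surface_mesh(fit$surface$vertices, subs[[L]]$triangles, check = FALSE)
    cs <- mesh_cross_section(sm, plane)
    for (cv in cs) {
      if (nrow(cv$points) < 3) next
      xy <- world_to_plane(plane, cv$points)$xy
      out[[length(out) + 1L]] <- labelled_contour(L, xy, closed = cv$closed,
                                                  slice_id = plane$id)
    }
  }
  out
}

#' Stage-C: re-align each slice rigidly to the fitted shape model
#'
#' Per slice, minimises the mean label-matched distance from its transformed
#' contour points to the fitted model surface over all six rigid parameters
#' (through-plane translation and tilts now free), sequentially for all LAX
#' then all SAX slices. Accepted updates never increase the per-slice
#' objective. Slices without contours are left unchanged.
#'
#' @param planes list of `slice_plane`s (original poses).
#' @param contours per-slice lists of [labelled_contour()]s.
#' @param fit an [fit_ssm()] result.
#' @param thetas0 stage-B poses as initialisation.
#' @param bounds `c(max |translation| mm, max |rotation| deg)`.
#' @param step0 initial pattern-search step (mm / deg).
#' @param step_min final step size.
#' @param max_points objective subsampling budget per contour.
#' @param pose_penalty quadratic pose-regulariser weights
#'   `(in-plane, out-of-plane)`: the in-plane directions (which the earlier
#'   stages fixed and the point-to-surface objective leaves nearly flat) are
#'   anchored harder than the through-plane motion this stage corrects.
#' @return list with `thetas` (6-DOF `rigid_params` per slice), `objective`
#'   (per-slice final mean distance), `unchanged` (slices without contours).
#' @export
align_slices_to_model <- function(planes, contours, fit, thetas0 = NULL,
                                  bounds = c(10, 15), step0 = 2, step_min = 0.1,
                                  max_points = 60,
                                  pose_penalty = c(inplane = 0.02, outplane = 0.002)) {
  n <- length(planes)
  thetas <- if (is.null(thetas0)) replicate(n, rigid_params(), simplify = FALSE) else thetas0
  layout <- classify_slices(planes)
  order_idx <- c(layout$lax_idx, layout$sax_idx)
  vlab <- fit$vertex_labels
  subs <- .label_submeshes(fit$surface$vertices, fit$surface$triangles, vlab)
  bvhs <- lapply(subs, function(s)
    mesh_bvh(surface_mesh(fit$surface$vertices, s$triangles, check = FALSE)))
  objective <- rep(NA_real_, n)
  unchanged <- integer(0)
  for (i in order_idx) {
    cons <- contours[[i]]
    if (length(cons) == 0) { unchanged <- c(unchanged, i); next }
    labs <- vapply(cons, `[[`, character(1), "label")
    mlabs <- .model_label_map[labs]
    keep <- !is.na(mlabs) & mlabs %in% names(bvhs)
    if (!any(keep)) { unchanged <- c(unchanged, i); next }
    cons <- cons[keep]; mlabs <- mlabs[keep]
    # subsample each contour for the objective (uniform along the polyline)
    cons_obj <- lapply(cons, function(cc) {
      if (nrow(cc$points) <= max_points) return(cc)
      cc$points <- cc$points[round(seq(1, nrow(cc$points), length.out = max_points)), ]
      cc
    })
    base_theta <- thetas[[i]]
    # base pose composed with a 6-DOF correction
    eval_par <- function(p) {
      th <- compose_rigid(base_theta,
                          rigid_params(p[1], p[2], p[3], p[4], p[5], p[6]),
                          planes[[i]])
      pl <- apply_rigid(planes[[i]], th)
      tot <- 0; m <- 0L
      for (ci in seq_along(cons_obj)) {
        P3 <- contour_to_3d(cons_obj[[ci]], pl)
        d <- point_to_mesh_distance(P3, bvhs[[mlabs[ci]]])
        tot <- tot + sum(d); m <- m + length(d)
      }
      # a small pose penalty anchors the directions the surface distance
      # leaves flat; in-plane motion (already fixed by the earlier stages) is
      # anchored harder than the out-of-plane motion this stage corrects
      tot / m +
        pose_penalty[1] * (p[1]^2 + p[2]^2 + (0.5 * p[6])^2) +
        pose_penalty[2] * (p[3]^2 + (0.5 * p[4])^2 + (0.5 * p[5])^2)
    }
    res <- .hooke_jeeves(rep(0, 6), eval_par,
                         steps0 = rep(step0, 6), step_min = step_min,
                         lower = c(rep(-bounds[1], 3), rep(-bounds[2], 3)),
                         upper = c(rep(bounds[1], 3), rep(bounds[2], 3)))
    p <- res$par
    thetas[[i]] <- compose_rigid(base_theta,
                                 rigid_params(p[1], p[2], p[3], p[4], p[5], p[6]),
                                 planes[[i]])
    objective[i] <- res$value
  }
  list(thetas = thetas, objective = objective, unchanged = unchanged)
}
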