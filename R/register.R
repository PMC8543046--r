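# The slice-consistency objective and its optimiser. The global motion (GM)
# discrepancy is the sum of a pluggable pairwise dissimilarity E over all
# intersecting slice pairs; it is minimised by sequentially re-posing one
# slice at a time (bounded in-plane pattern search), long-axis slices first.

#' Sample paired intensity profiles along a slice intersection line
#'
#' Both images are sampled bilinearly at identical 3D points along the line,
#' clipped to the overlap of both pixel grids. Samples falling on invalid
#' (NA) pixels in either image are masked in both.
#'
#' @param plane_a,plane_b `slice_plane`s at their current poses.
#' @param img_a,img_b matrices defined on the planes' pixel grids (e.g. local
#'   phase images). Defaults to the planes' own pixels.
#' @param line their intersection [line3d()] (computed when NULL).
#' @param step sample spacing along the line, mm.
#' @param min_samples minimum number of valid samples; shorter overlaps are
#'   rejected.
#' @return list with `a`, `b` (equal-length sample vectors), `t` (line
#'   parameter), `step`, and `endpoints` (2 x 3) — or `NULL` when the overlap
#'   is too short (the pair is skipped).
#' @export
sample_profiles <- function(plane_a, plane_b, img_a = plane_a$pixels,
                            img_b = plane_b$pixels, line = NULL,
                            step = 0.5 * min(plane_a$spacing, plane_b$spacing),
                            min_samples = 10) {
  if (is.null(line)) line <- plane_intersection_line(plane_a, plane_b)
  if (is.null(line)) return(NULL)
  rng_a <- .line_plane_range(plane_a, line)
  rng_b <- .line_plane_range(plane_b, line)
  if (is.null(rng_a) || is.null(rng_b)) return(NULL)
  t0 <- max(rng_a[1], rng_b[1]); t1 <- min(rng_a[2], rng_b[2])
  if (t1 - t0 < (min_samples - 1) * step) return(NULL)
  ts <- seq(t0, t1, by = step)
  sa <- .sample_on_plane(plane_a, img_a, line, ts)
  sb <- .sample_on_plane(plane_b, img_b, line, ts)
  ok <- !is.na(sa) & !is.na(sb)
  if (sum(ok) < min_samples) return(NULL)
  list(a = sa[ok], b = sb[ok], t = ts[ok], step = step,
       endpoints = rbind(line$point + t0 * line$direction,
                         line$point + t1 * line$direction))
}

# parameter interval of a 3D line clipped to a plane's pixel rectangle
.line_plane_range <- function(plane, line) {
  pr <- world_to_plane(plane, rbind(line$point))
  p0 <- pr$xy[1, ]
  d <- c(sum(line$direction * plane$u_axis), sum(line$direction * plane$v_axis))
  ext <- c((plane$shape[2] - 1) * plane$spacing[1],
           (plane$shape[1] - 1) * plane$spacing[2])
  t0 <- -Inf; t1 <- Inf
  for (k in 1:2) {
    if (abs(d[k]) < 1e-12) {
      if (p0[k] < 0 || p0[k] > ext[k]) return(NULL)
    } else {
      ta <- (0 - p0[k]) / d[k]; tb <- (ext[k] - p0[k]) / d[k]
      t0 <- max(t0, min(ta, tb)); t1 <- min(t1, max(ta, tb))
    }
  }
  if (!is.finite(t0) || !is.finite(t1) || t1 <= t0) return(NULL)
  c(t0, t1)
}

.sample_on_plane <- function(plane, img, line, ts) {
  pts <- outer(ts, line$direction)
  pts <- sweep(pts, 2, line$point, `+`)
  pr <- world_to_plane(plane, pts)
  cpp_bilinear(img, pr$xy[, 1] / plane$spacing[1], pr$xy[, 2] / plane$spacing[2])
}

#' Normalized cross-correlation of a profile pair
#'
#' Pearson-type correlation in [-1, 1]; invariant to affine intensity changes
#' of either profile. The dissimilarity used by the registration is `1 - NCC`.
#'
#' @param a,b equal-length numeric vectors, or a list with elements `a`, `b`
#'   as returned by [sample_profiles()].
#' @return correlation, or `NA` when fewer than 2 samples or zero variance
#'   (the pair is skipped).
#' @export
ncc <- function(a, b = NULL) {
  if (is.list(a)) { b <- a$b; a <- a$a }
  ok <- !is.na(a) & !is.na(b)
  a <- a[ok]; b <- b[ok]
  if (length(a) < 2) return(NA_real_)
  if (sd(a) == 0 || sd(b) == 0) return(NA_real_)
  cor(a, b)
}

#' Global motion discrepancy (sum of pairwise dissimilarities)
#'
#' `GM = sum over intersecting pairs (i, j) of E(S_i^{theta_i}, S_j^{theta_j})`.
#' Pairs skipped by the dissimilarity (no admissible overlap) are excluded and
#' counted.
#'
#' @param planes list of `slice_plane`s (original poses).
#' @param thetas list of `rigid_params`, one per slice (NULL = identities).
#' @param dissim function `(plane_i, plane_j, data_i, data_j) -> scalar or NA`.
#' @param data per-slice payload passed to `dissim` (phase images, contours...).
#' @return list with `gm`, `n_pairs`, `n_skipped`.
#' @export
global_motion <- function(planes, thetas = NULL, dissim, data = NULL) {
  n <- length(planes)
  if (is.null(thetas)) thetas <- replicate(n, rigid_params(), simplify = FALSE)
  pt <- mapply(apply_rigid, planes, thetas, SIMPLIFY = FALSE)
  gm <- 0; used <- 0L; skipped <- 0L
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    e <- dissim(pt[[i]], pt[[j]], data[[i]], data[[j]])
    if (is.na(e)) skipped <- skipped + 1L
    else { gm <- gm + e; used <- used + 1L }
  }
  if (used == 0L && n > 1)
    stop("objective undefined: no admissible intersecting slice pair", call. = FALSE)
  list(gm = gm, n_pairs = used, n_skipped = skipped)
}

# partial GM terms involving slice i
.partial_gm <- function(i, planes_t, dissim, data) {
  s <- 0; any_pair <- FALSE
  for (j in seq_along(planes_t)) {
    if (j == i) next
    e <- dissim(planes_t[[i]], planes_t[[j]], data[[i]], data[[j]])
    if (!is.na(e)) { s <- s + e; any_pair <- TRUE }
  }
  if (!any_pair) NA_real_ else s
}

# Hooke-Jeeves pattern search (shared by the in-plane and 6-DOF stages):
# sequential exploratory probes around the base point, followed by pattern
# moves along the accumulated direction of improvement; steps halve when no
# exploratory move succeeds. Handles the diagonal valleys that coupled
# translation/rotation objectives produce.
.hooke_jeeves <- function(par0, fn, steps0, step_min, lower, upper,
                          polish = TRUE) {
  clamp <- function(p) pmin(pmax(p, lower), upper)
  explore <- function(p, v, steps) {
    for (k in seq_along(p)) {
      for (s in c(1, -1)) {
        cand <- p
        cand[k] <- min(upper[k], max(lower[k], cand[k] + s * steps[k]))
        if (cand[k] == p[k]) next
        vc <- fn(cand)
        if (!is.na(vc) && vc < v - 1e-12) { p <- cand; v <- vc; break }
      }
    }
    list(p = p, v = v)
  }
  par <- clamp(par0)
  base <- fn(par)
  if (is.na(base)) return(list(par = par, value = NA_real_))
  steps <- steps0
  while (max(steps) >= step_min) {
    ex <- explore(par, base, steps)
    if (ex$v < base - 1e-12) {
      repeat {
        pattern <- clamp(2 * ex$p - par)
        par <- ex$p; base <- ex$v
        vpat <- fn(pattern)
        ex2 <- explore(pattern, if (is.na(vpat)) Inf else vpat, steps)
        if (!is.na(ex2$v) && ex2$v < base - 1e-12) ex <- ex2 else break
      }
    } else {
      steps <- steps / 2
    }
  }
  # simplex polish: axis-aligned probes stall in the diagonal valleys that the
  # coupled translation/rotation objective produces; a short Nelder-Mead run
  # from the pattern-search point is kept only when it improves
  if (!polish) return(list(par = par, value = base))
  pol <- tryCatch(
    stats::optim(par, function(p) {
      v <- fn(clamp(p))
      if (is.na(v)) 1e6 else v
    }, method = "Nelder-Mead",
    control = list(maxit = 80 * length(par), reltol = 1e-8,
                   parscale = pmax(steps0, 1e-3))),
    error = function(e) NULL)
  if (!is.null(pol) && !is.na(pol$value) && pol$value < base - 1e-12) {
    par <- clamp(pol$par)
    base <- fn(par)
  }
  list(par = par, value = base)
}

# bounded pattern search over the in-plane parameters of slice i
.pattern_search_inplane <- function(i, planes, planes_t, thetas, dissim, data,
                                    bounds, step0, step_min, polish = FALSE) {
  theta <- thetas[[i]]
  par <- c(theta$tx, theta$ty, theta$gamma)
  eval_par <- function(p) {
    th <- rigid_inplane(p[1], p[2], p[3])
    pti <- apply_rigid(planes[[i]], th)
    tmp <- planes_t
    tmp[[i]] <- pti
    .partial_gm(i, tmp, dissim, data)
  }
  lim <- c(bounds[1], bounds[1], bounds[2])
  res <- .hooke_jeeves(par, eval_par, step0, step_min, -lim, lim, polish = polish)
  if (is.na(res$value)) return(list(theta = theta, value = NA_real_, changed = FALSE))
  list(theta = rigid_inplane(res$par[1], res$par[2], res$par[3]),
       value = res$value, changed = !identical(res$par, par))
}

#' Sequential per-slice minimisation of the global motion discrepancy
#'
#' Iteratively optimises the in-plane rigid parameters `(tx, ty, gamma)` of
#' one slice at a time by bounded derivative-free pattern search, keeping the
#' others fixed; accepted updates never increase GM. Long-axis slices are
#' registered first, then all slices together. One multi-start restart from
#' the stage-input pose guards against early local minima.
#'
#' @param planes list of `slice_plane`s at their stage-input poses.
#' @param dissim pairwise dissimilarity `(plane_i, plane_j, data_i, data_j)`.
#' @param data per-slice payload for `dissim`.
#' @param lax_idx indices of long-axis slices (registered first).
#' @param thetas0 initial parameters (default identities).
#' @param bounds `c(max |translation| mm, max |rotation| deg)`.
#' @param tol stop a phase when a full sweep improves GM by less than this.
#' @param max_sweeps per phase.
#' @param lax_sweeps sweeps over the LAX-only subset before the joint phase.
#' @param step0 initial pattern-search steps `(tx mm, ty mm, gamma deg)`.
#' @param step_min smallest step before a slice's search stops.
#' @param restart re-run each slice once from its stage-input pose at the end
#'   and keep the better pose.
#' @return list with `thetas`, `gm_trace` (GM after each sweep, non-increasing),
#'   `skipped` (slices without admissible pairs).
#' @export
optimize_slicewise <- function(planes, dissim, data = NULL, lax_idx = integer(0),
                               thetas0 = NULL, bounds = c(10, 15), tol = 1e-4,
                               max_sweeps = 10, lax_sweeps = 2,
                               step0 = c(2, 2, 3), step_min = 0.1,
                               restart = TRUE) {
  n <- length(planes)
  thetas <- if (is.null(thetas0)) replicate(n, rigid_inplane(), simplify = FALSE) else thetas0
  planes_t <- mapply(apply_rigid, planes, thetas, SIMPLIFY = FALSE)
  gm0 <- global_motion(planes, thetas, dissim, data)
  trace <- gm0$gm
  skipped <- integer(0)
  sweep_set <- function(idx, sweeps, polish = FALSE) {
    for (sw in seq_len(sweeps)) {
      before <- trace[length(trace)]
      for (i in idx) {
        res <- .pattern_search_inplane(i, planes, planes_t, thetas, dissim, data,
                                       bounds, step0, step_min, polish = polish)
        if (is.na(res$value)) { skipped <<- union(skipped, i); next }
        thetas[[i]] <<- res$theta
        planes_t[[i]] <<- apply_rigid(planes[[i]], res$theta)
      }
      gm <- global_motion(planes, thetas, dissim, data)$gm
      trace <<- c(trace, min(gm, before))
      if (before - gm < tol) break
    }
  }
  if (length(lax_idx) > 0 && length(lax_idx) < n) sweep_set(lax_idx, lax_sweeps)
  sweep_set(seq_len(n), max_sweeps)
  # one polishing sweep with the simplex refinement enabled
  sweep_set(seq_len(n), 1, polish = TRUE)
  if (restart) {
    # one multi-start pass from the stage-input pose
    improved <- FALSE
    for (i in seq_len(n)) {
      if (i %in% skipped) next
      cur <- .partial_gm(i, planes_t, dissim, data)
      base_thetas <- thetas; base_planes <- planes_t
      base_thetas[[i]] <- if (is.null(thetas0)) rigid_inplane() else thetas0[[i]]
      base_planes[[i]] <- apply_rigid(planes[[i]], base_thetas[[i]])
      res <- .pattern_search_inplane(i, planes, base_planes, base_thetas, dissim,
                                     data, bounds, step0, step_min)
      if (!is.na(res$value) && !is.na(cur) && res$value < cur - 1e-9) {
        thetas[[i]] <- res$theta
        planes_t[[i]] <- apply_rigid(planes[[i]], res$theta)
        improved <- TRUE
      }
    }
    if (improved) {
      gm <- global_motion(planes, thetas, dissim, data)$gm
      trace <- c(trace, min(gm, trace[length(trace)]))
    }
  }
  list(thetas = thetas, gm_trace = trace, skipped = skipped)
}

# ---------------------------------------------------------------------------
# Stage A: intensity (local phase) dissimilarity

#' Stage-A intensity-based misalignment correction
#'
#' Computes a local-phase image per slice once (filtering is unaffected by
#' in-plane re-posing, which only moves the sampling line), then minimises the
#' global motion discrepancy with `E = 1 - NCC` of the phase profiles along
#' each slice-intersection line.
#'
#' @param planes list of `slice_plane`s with pixels.
#' @param params a [filter_bank_params()].
#' @param step profile sample spacing, mm (default half the finest pixel
#'   spacing).
#' @param min_samples minimum valid profile length.
#' @param ... passed to [optimize_slicewise()].
#' @return list with `thetas`, `gm_trace`, `skipped`, `layout`.
#' @export
correct_intensity <- function(planes, params = filter_bank_params(),
                              step = NULL, min_samples = 10, ...) {
  layout <- classify_slices(planes)
  phases <- lapply(planes, function(p) {
    if (is.null(p$pixels)) return(NULL)
    lp <- local_phase_image(p$pixels, params)
    lp$phase
  })
  if (is.null(step)) step <- 0.5 * min(vapply(planes, function(p) min(p$spacing), 1))
  dissim <- function(pa, pb, da, db) {
    if (is.null(da) || is.null(db)) return(NA_real_)
    cpp_profile_pair_E(pa$origin, pa$u_axis, pa$v_axis, pa$spacing, pa$shape, da,
                       pb$origin, pb$u_axis, pb$v_axis, pb$spacing, pb$shape, db,
                       step, as.integer(min_samples))
  }
  res <- optimize_slicewise(planes, dissim, data = phases,
                            lax_idx = layout$lax_idx, ...)
  res$layout <- layout
  res
}
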