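# Analytic biventricular phantom: nested truncated-ellipsoid left ventricle
# and a crescent-shaped right ventricle formed by a laterally offset ellipsoid
# clipped to the outside of the LV epicardium. The phantom provides exact
# implicit surfaces, simulated cine slices with ground-truth label masks,
# analytic contours, seeded misalignment injection, and the population used
# to build the synthetic shape model.

#' Phantom specification
#'
#' Geometry and imaging parameters of the synthetic biventricular phantom.
#' The LV is the region between two concentric ellipsoids; the RV cavity is
#' the part of a laterally offset ellipsoid lying outside the LV epicardium,
#' which creates a genuine septum (the shared wall), and the thin RV free wall
#' is a uniform outward offset of that ellipsoid. Everything is truncated at
#' the basal plane `z = base_height`.
#'
#' @param lv_semi_axes LV endocardial semi-axes (mm), apex along -z.
#' @param lv_wall LV wall thickness added to each semi-axis (mm).
#' @param rv_offset centre of the RV ellipsoid relative to the LV centre (mm).
#' @param rv_semi_axes RV endocardial ellipsoid semi-axes (mm).
#' @param rv_wall synthetic RV wall thickness (mm); 3 mm matches the thin RV
#'   free wall that cine MR cannot resolve.
#' @param base_height basal truncation plane `z = base_height` (mm).
#' @param intensity intensity levels `(background, myocardium, blood pool)`.
#' @param noise_sd Gaussian pixel noise SD (intensity units).
#' @param seed default seed for stochastic operations on this phantom.
#' @return object of class `phantom_spec`.
#' @export
phantom_spec <- function(lv_semi_axes = c(25, 25, 54),
                         lv_wall = 8,
                         rv_offset = c(20, 0, -6),
                         rv_semi_axes = c(34, 27, 46),
                         rv_wall = 3,
                         base_height = 32,
                         intensity = c(background = 40, myocardium = 110, blood = 190),
                         noise_sd = 4,
                         seed = 1L) {
  stopifnot(length(lv_semi_axes) == 3, all(lv_semi_axes > 0),
            lv_wall > 0, rv_wall > 0, length(rv_offset) == 3)
  if (!is.null(rv_semi_axes))
    stopifnot(length(rv_semi_axes) == 3, all(rv_semi_axes > 0))
  if (length(unique(intensity)) != 3)
    stop("intensity levels must be distinct", call. = FALSE)
  spec <- structure(list(lv_semi_axes = as.numeric(lv_semi_axes),
                         lv_wall = as.numeric(lv_wall),
                         rv_offset = as.numeric(rv_offset),
                         rv_semi_axes = if (is.null(rv_semi_axes)) NULL else as.numeric(rv_semi_axes),
                         rv_wall = as.numeric(rv_wall),
                         base_height = as.numeric(base_height),
                         intensity = intensity,
                         noise_sd = as.numeric(noise_sd),
                         seed = as.integer(seed)),
                    class = "phantom_spec")
  if (.has_rv(spec)) {
    # the RV ellipsoid must poke out of the LV epicardium (else no cavity) and
    # must genuinely overlap it (else no septum)
    imp <- phantom_implicits(spec)
    probe <- seq(-1, 1, length.out = 81)
    ax <- spec$rv_offset[1] + probe * spec$rv_semi_axes[1]
    pts <- cbind(ax, spec$rv_offset[2], spec$rv_offset[3])
    inside_rv <- imp$rv_endo(pts) < 0
    if (!any(inside_rv & imp$lv_epi(pts) > 0))
      stop("degenerate phantom: RV ellipsoid entirely inside the LV epicardium",
           call. = FALSE)
    if (!any(inside_rv & imp$lv_epi(pts) < 0))
      stop("self-intersecting phantom: RV ellipsoid does not overlap the LV",
           call. = FALSE)
  }
  spec
}

.has_rv <- function(spec) !is.null(spec$rv_semi_axes) && all(is.finite(spec$rv_semi_axes)) && spec$rv_semi_axes[1] > 0

#' @export
print.phantom_spec <- function(x, ...) {
  cat(sprintf("<phantom_spec LV endo (%s) mm, wall %g mm, RV %s, base z = %g>\n",
              paste(x$lv_semi_axes, collapse = ", "), x$lv_wall,
              if (.has_rv(x)) sprintf("semi (%s) at (%s)",
                                      paste(x$rv_semi_axes, collapse = ", "),
                                      paste(x$rv_offset, collapse = ", "))
              else "absent", x$base_height))
  invisible(x)
}

#' A phantom without a right ventricle (degenerate test geometry)
#' @param lv_semi_axes,lv_wall,base_height see [phantom_spec()].
#' @export
phantom_spec_lv_only <- function(lv_semi_axes = c(25, 25, 25), lv_wall = 8,
                                 base_height = Inf) {
  phantom_spec(lv_semi_axes = lv_semi_axes, lv_wall = lv_wall,
               base_height = base_height, rv_semi_axes = NULL)
}

# quadratic ellipsoid value and an approximately metric (signed-distance-like)
# normalisation q / |grad q|
.ellip_q <- function(pts, ctr, semi) {
  d <- sweep(rbind(pts), 2, ctr)
  (d[, 1] / semi[1])^2 + (d[, 2] / semi[2])^2 + (d[, 3] / semi[3])^2 - 1
}

.ellip_qn <- function(pts, ctr, semi) {
  pts <- rbind(pts)
  d <- sweep(pts, 2, ctr)
  q <- (d[, 1] / semi[1])^2 + (d[, 2] / semi[2])^2 + (d[, 3] / semi[3])^2 - 1
  g <- sqrt((2 * d[, 1] / semi[1]^2)^2 + (2 * d[, 2] / semi[2]^2)^2 +
              (2 * d[, 3] / semi[3]^2)^2)
  q / pmax(g, 1e-12)
}

#' Analytic implicit surfaces of the phantom
#'
#' Vectorised signed functions, negative inside, approximately in mm near the
#' zero level. `heart` is the full epicardial solid (union of LV epicardial
#' ellipsoid and RV outer ellipsoid), `rv_cavity` the crescent RV blood pool.
#' Basal truncation is not baked in; combine with `z <= base_height`.
#'
#' @param spec a [phantom_spec()].
#' @return list of functions `lv_endo`, `lv_epi`, `rv_endo`, `rv_epi`,
#'   `rv_cavity`, `heart`, each mapping an n x 3 matrix to n signed values.
#' @export
phantom_implicits <- function(spec) {
  a_endo <- spec$lv_semi_axes
  a_epi <- spec$lv_semi_axes + spec$lv_wall
  ctr <- c(0, 0, 0)
  rvc <- spec$rv_offset
  a_rv <- spec$rv_semi_axes
  a_rv3 <- spec$rv_semi_axes + spec$rv_wall
  has_rv <- .has_rv(spec)
  list(
    lv_endo = function(p) .ellip_qn(p, ctr, a_endo),
    lv_epi = function(p) .ellip_qn(p, ctr, a_epi),
    rv_endo = function(p) if (has_rv) .ellip_qn(p, rvc, a_rv) else rep(Inf, nrow(rbind(p))),
    rv_epi = function(p) if (has_rv) .ellip_qn(p, rvc, a_rv3) else rep(Inf, nrow(rbind(p))),
    rv_cavity = function(p) {
      if (!has_rv) return(rep(Inf, nrow(rbind(p))))
      pmax(.ellip_qn(p, rvc, a_rv), -.ellip_qn(p, ctr, a_epi))
    },
    heart = function(p) {
      f <- .ellip_qn(p, ctr, a_epi)
      if (has_rv) f <- pmin(f, .ellip_qn(p, rvc, a_rv3))
      f
    }
  )
}

# Newton projection of points onto the zero level of an implicit, moving along
# the numeric gradient restricted to `dirs` (k x 3 rows spanning the allowed
# subspace; NULL = full 3D).
.project_implicit <- function(pts, f, dirs = NULL, iters = 6, h = 1e-4) {
  pts <- rbind(pts)
  for (it in seq_len(iters)) {
    v <- f(pts)
    if (all(abs(v) < 1e-10)) break
    if (is.null(dirs)) {
      gx <- (f(sweep(pts, 2, c(h, 0, 0), "+")) - v) / h
      gy <- (f(sweep(pts, 2, c(0, h, 0), "+")) - v) / h
      gz <- (f(sweep(pts, 2, c(0, 0, h), "+")) - v) / h
      g2 <- gx^2 + gy^2 + gz^2
      step <- v / pmax(g2, 1e-12)
      pts <- pts - cbind(step * gx, step * gy, step * gz)
    } else {
      g <- matrix(0, nrow(pts), nrow(dirs))
      for (k in seq_len(nrow(dirs)))
        g[, k] <- (f(pts + matrix(dirs[k, ] * h, nrow(pts), 3, byrow = TRUE)) - v) / h
      g2 <- rowSums(g^2)
      step <- v / pmax(g2, 1e-12)
      pts <- pts - (g * step) %*% dirs
    }
  }
  pts
}

# ---------------------------------------------------------------------------
# Ground-truth surface meshes

# radial distance from the z-axis point (0,0,z) along direction theta to the
# epicardial union boundary (closed form per ellipsoid)
.union_radius <- function(theta, z, spec) {
  a_epi <- spec$lv_semi_axes + spec$lv_wall
  w2 <- 1 - (z / a_epi[3])^2
  r_lv <- if (w2 > 0) {
    A <- a_epi[1] * sqrt(w2); B <- a_epi[2] * sqrt(w2)
    A * B / sqrt((B * cos(theta))^2 + (A * sin(theta))^2)
  } else rep(-Inf, length(theta))
  r <- r_lv
  if (.has_rv(spec)) {
    a3 <- spec$rv_semi_axes + spec$rv_wall
    wz <- 1 - ((z - spec$rv_offset[3]) / a3[3])^2
    if (wz > 0) {
      A <- a3[1] * sqrt(wz); B <- a3[2] * sqrt(wz)
      cx <- spec$rv_offset[1]; cy <- spec$rv_offset[2]
      # largest positive root of ((t c - cx)/A)^2 + ((t s - cy)/B)^2 = 1
      ct <- cos(theta); st <- sin(theta)
      qa <- (ct / A)^2 + (st / B)^2
      qb <- -2 * (ct * cx / A^2 + st * cy / B^2)
      qc <- (cx / A)^2 + (cy / B)^2 - 1
      disc <- qb^2 - 4 * qa * qc
      t2 <- ifelse(disc >= 0, (-qb + sqrt(pmax(disc, 0))) / (2 * qa), -Inf)
      r <- pmax(r, t2)
    }
  }
  r
}

# closed RV cavity cross-section loop at height z (2D xy), or NULL. The
# free-wall/septal transition angles are refined by bisection so the loop
# depends smoothly on the shape parameters (important for the PCA population).
.rv_section_loop <- function(z, spec, n_probe = 512) {
  if (!.has_rv(spec)) return(NULL)
  a_rv <- spec$rv_semi_axes
  a_epi <- spec$lv_semi_axes + spec$lv_wall
  wz2 <- 1 - ((z - spec$rv_offset[3]) / a_rv[3])^2
  if (wz2 <= 1e-9) return(NULL)
  A <- a_rv[1] * sqrt(wz2); B <- a_rv[2] * sqrt(wz2)
  cx <- spec$rv_offset[1]; cy <- spec$rv_offset[2]
  we2 <- 1 - (z / a_epi[3])^2
  n_half <- n_probe %/% 2
  if (we2 <= 0) {
    phi <- seq(0, 2 * pi, length.out = n_probe + 1)[-(n_probe + 1)]
    return(cbind(cx + A * cos(phi), cy + B * sin(phi)))
  }
  Ae <- a_epi[1] * sqrt(we2); Be <- a_epi[2] * sqrt(we2)
  # signed "outside LV" value along the RV ellipse
  f_rv <- function(phi) ((cx + A * cos(phi)) / Ae)^2 + ((cy + B * sin(phi)) / Be)^2 - 1
  phi <- seq(0, 2 * pi, length.out = n_probe + 1)[-(n_probe + 1)]
  out_lv <- f_rv(phi) > 0
  if (!any(out_lv)) return(NULL)
  if (all(out_lv)) {
    return(cbind(cx + A * cos(phi), cy + B * sin(phi)))
  }
  bisect <- function(f, lo, hi) {
    for (it in 1:40) {
      mid <- (lo + hi) / 2
      if (f(lo) * f(mid) <= 0) hi <- mid else lo <- mid
    }
    (lo + hi) / 2
  }
  # the single free-wall arc: refine its two endpoints
  first_in <- which(!out_lv)[1]
  ord <- ((seq_len(n_probe) + first_in - 2L) %% n_probe) + 1L
  mask <- out_lv[ord]
  runs <- rle(mask)
  start <- cumsum(c(1, runs$lengths))[which(runs$values)[1]]
  len <- runs$lengths[which(runs$values)[1]]
  phi_lo_grid <- phi[ord[start]] - 2 * pi / n_probe
  phi_hi_grid <- phi[ord[start + len - 1L]]
  phi_a <- bisect(f_rv, phi_lo_grid, phi_lo_grid + 2 * pi / n_probe)
  phi_b <- bisect(f_rv, phi_hi_grid, phi_hi_grid + 2 * pi / n_probe)
  if (phi_b < phi_a) phi_b <- phi_b + 2 * pi
  pf <- seq(phi_a, phi_b, length.out = n_half)
  free_arc <- cbind(cx + A * cos(pf), cy + B * sin(pf))
  # the septal arc on the LV epicardial ellipse: refine likewise
  f_lv <- function(psi) ((Ae * cos(psi) - cx) / A)^2 + ((Be * sin(psi) - cy) / B)^2 - 1
  psi <- phi
  in_rv <- f_lv(psi) < 0
  if (!any(in_rv)) return(NULL)
  first_out <- which(!in_rv)[1]
  ord2 <- ((seq_len(n_probe) + first_out - 2L) %% n_probe) + 1L
  mask2 <- in_rv[ord2]
  runs2 <- rle(mask2)
  start2 <- cumsum(c(1, runs2$lengths))[which(runs2$values)[1]]
  len2 <- runs2$lengths[which(runs2$values)[1]]
  psi_lo_grid <- psi[ord2[start2]] - 2 * pi / n_probe
  psi_hi_grid <- psi[ord2[start2 + len2 - 1L]]
  psi_a <- bisect(f_lv, psi_lo_grid, psi_lo_grid + 2 * pi / n_probe)
  psi_b <- bisect(f_lv, psi_hi_grid, psi_hi_grid + 2 * pi / n_probe)
  if (psi_b < psi_a) psi_b <- psi_b + 2 * pi
  ps <- seq(psi_a, psi_b, length.out = n_half)
  sept_arc <- cbind(Ae * cos(ps), Be * sin(ps))
  # orient the septal arc to continue from the free arc's end
  tail_pt <- free_arc[nrow(free_arc), ]
  d_fwd <- sum((sept_arc[1, ] - tail_pt)^2)
  d_rev <- sum((sept_arc[nrow(sept_arc), ] - tail_pt)^2)
  if (d_rev < d_fwd) sept_arc <- sept_arc[rev(seq_len(nrow(sept_arc))), , drop = FALSE]
  rbind(free_arc, sept_arc)
}

.loft_rings <- function(rings, apex = NULL, cap_top = TRUE) {
  # rings: list of k x 3 matrices with identical k, ordered apex -> base
  n <- nrow(rings[[1]])
  V <- do.call(rbind, rings)
  F <- list()
  for (r in seq_len(length(rings) - 1)) {
    o1 <- (r - 1) * n; o2 <- r * n
    j <- seq_len(n); j2 <- c(2:n, 1)
    F[[length(F) + 1L]] <- cbind(o1 + j, o1 + j2, o2 + j)
    F[[length(F) + 1L]] <- cbind(o1 + j2, o2 + j2, o2 + j)
  }
  if (!is.null(apex)) {
    V <- rbind(apex, V)
    F <- lapply(F, function(f) f + 1L)
    j <- seq_len(n); j2 <- c(2:n, 1)
    F[[length(F) + 1L]] <- cbind(1L, 1L + j2, 1L + j)
  }
  if (cap_top) {
    top <- rings[[length(rings)]]
    # ear-clip the basal lid in its own plane (use xy)
    tri <- .ear_clip(top[, 1:2, drop = FALSE])
    off <- nrow(V) - n
    F[[length(F) + 1L]] <- tri + off
  }
  mesh <- surface_mesh(V, do.call(rbind, F), check = FALSE)
  .orient_outward(mesh)
}

#' Ground-truth phantom surfaces
#'
#' Builds watertight triangle meshes of the LV endocardium, RV endocardium
#' (crescent) and the epicardial union boundary, all truncated and capped at
#' the basal plane, with vertices lying on the analytic implicit surfaces.
#'
#' @param spec a [phantom_spec()].
#' @param ring_spacing vertical ring distance, mm.
#' @param n_theta points per ring.
#' @return list with `lv_endo`, `rv_endo` (or NULL), `epi` surface meshes,
#'   the `implicits`, and `spec`.
#' @export
make_phantom_surfaces <- function(spec, ring_spacing = 1.5, n_theta = 96) {
  imp <- phantom_implicits(spec)
  a_endo <- spec$lv_semi_axes
  a_epi <- spec$lv_semi_axes + spec$lv_wall
  ellip_rings <- function(semi, zmax) {
    z_lo <- -semi[3]
    z_hi <- min(spec$base_height, zmax)
    truncated <- spec$base_height < zmax
    zs <- seq(z_lo + ring_spacing * 0.5, z_hi, by = ring_spacing)
    if (truncated && (length(zs) == 0 || max(zs) < z_hi - 1e-9)) zs <- c(zs, z_hi)
    theta <- seq(0, 2 * pi, length.out = n_theta + 1)[-(n_theta + 1)]
    rings <- lapply(zs, function(z) {
      w <- sqrt(max(1 - (z / semi[3])^2, 1e-8))
      cbind(semi[1] * w * cos(theta), semi[2] * w * sin(theta), z)
    })
    apex <- c(0, 0, z_lo)
    if (!truncated) {
      # full (untruncated) ellipsoid: close with the top apex
      rings <- c(rings, list(cbind(rep(0, n_theta) + 1e-6 * cos(theta),
                                   1e-6 * sin(theta), semi[3] - 1e-9)))
      m <- .loft_rings(rings, apex = apex, cap_top = TRUE)
    } else {
      m <- .loft_rings(rings, apex = apex, cap_top = TRUE)
    }
    m
  }
  lv_endo <- ellip_rings(a_endo, a_endo[3] - ring_spacing * 0.25)
  lv_endo$label <- "LV_ENDO"
  # epicardial union boundary
  z_lo <- -a_epi[3]
  z_hi <- min(spec$base_height, a_epi[3] - ring_spacing * 0.25)
  zs <- seq(z_lo + ring_spacing * 0.5, z_hi, by = ring_spacing)
  if (max(zs) < z_hi - 1e-9) zs <- c(zs, z_hi)
  theta <- seq(0, 2 * pi, length.out = n_theta + 1)[-(n_theta + 1)]
  epi_rings <- lapply(zs, function(z) {
    r <- .union_radius(theta, z, spec)
    cbind(r * cos(theta), r * sin(theta), z)
  })
  epi <- .loft_rings(epi_rings, apex = c(0, 0, z_lo), cap_top = TRUE)
  epi$label <- "EPI"
  rv_endo <- NULL
  if (.has_rv(spec)) {
    # locate the z-range where the crescent cavity exists
    rng <- tryCatch(.rv_cavity_zrange(spec), error = function(e) NULL)
    if (!is.null(rng)) {
      z0 <- rng[1]; z1 <- rng[2]
      zs <- seq(z0 + ring_spacing * 0.4, z1, by = ring_spacing)
      if (length(zs) >= 2) {
        rings <- lapply(zs, function(z) {
          loop <- .rv_section_loop(z, spec)
          P <- .resample_polyline(loop, n = n_theta, closed = TRUE)
          cbind(P, z)
        })
        bottom <- .project_implicit(matrix(c(colMeans(rings[[1]][, 1:2]), z0 - 0.2), 1),
                                    imp$rv_cavity)
        top_closed <- z1 < spec$base_height - 1
        if (top_closed) {
          tip <- .project_implicit(matrix(c(colMeans(rings[[length(rings)]][, 1:2]), z1 + 0.2), 1),
                                   imp$rv_cavity)
          n <- nrow(rings[[1]])
          V <- rbind(as.numeric(bottom), do.call(rbind, rings), as.numeric(tip))
          F <- list()
          j <- seq_len(n); j2 <- c(2:n, 1)
          F[[1]] <- cbind(1L, 1L + j2, 1L + j)
          for (r in seq_len(length(rings) - 1)) {
            o1 <- 1 + (r - 1) * n; o2 <- 1 + r * n
            F[[length(F) + 1L]] <- cbind(o1 + j, o1 + j2, o2 + j)
            F[[length(F) + 1L]] <- cbind(o1 + j2, o2 + j2, o2 + j)
          }
          off <- 1 + (length(rings) - 1) * n
          F[[length(F) + 1L]] <- cbind(nrow(V), off + j, off + j2)
          rv_endo <- .orient_outward(surface_mesh(V, do.call(rbind, F), check = FALSE))
        } else {
          n <- nrow(rings[[1]])
          V <- rbind(as.numeric(bottom), do.call(rbind, rings))
          F <- list()
          j <- seq_len(n); j2 <- c(2:n, 1)
          F[[1]] <- cbind(1L, 1L + j2, 1L + j)
          for (r in seq_len(length(rings) - 1)) {
            o1 <- 1 + (r - 1) * n; o2 <- 1 + r * n
            F[[length(F) + 1L]] <- cbind(o1 + j, o1 + j2, o2 + j)
            F[[length(F) + 1L]] <- cbind(o1 + j2, o2 + j2, o2 + j)
          }
          top <- rings[[length(rings)]]
          tri <- .ear_clip(top[, 1:2, drop = FALSE])
          F[[length(F) + 1L]] <- tri + 1 + (length(rings) - 1) * n
          rv_endo <- .orient_outward(surface_mesh(V, do.call(rbind, F), check = FALSE))
        }
        rv_endo$label <- "RV_ENDO"
      }
    }
  }
  list(lv_endo = lv_endo, rv_endo = rv_endo, epi = epi,
       implicits = imp, spec = spec)
}

# ---------------------------------------------------------------------------
# Region model, slicing and masks

# mask classes: 0 background, 1 LV cavity, 2 LV myocardium, 3 RV cavity
.phantom_classify <- function(pts, spec, imp = phantom_implicits(spec)) {
  pts <- rbind(pts)
  cls <- integer(nrow(pts))
  below <- pts[, 3] <= spec$base_height
  lv_en <- imp$lv_endo(pts) < 0 & below
  lv_ep <- imp$lv_epi(pts) < 0 & below
  rv_cav <- imp$rv_cavity(pts) < 0 & below
  cls[lv_ep] <- 2L
  cls[lv_en] <- 1L
  cls[rv_cav] <- 3L
  cls
}

.phantom_intensity_class <- function(pts, spec, imp = phantom_implicits(spec)) {
  # like classify but the thin RV wall images as myocardium
  pts <- rbind(pts)
  cls <- .phantom_classify(pts, spec, imp)
  below <- pts[, 3] <= spec$base_height
  rv_wall <- imp$rv_epi(pts) < 0 & imp$rv_endo(pts) >= 0 & imp$lv_epi(pts) >= 0 & below
  out <- rep(spec$intensity[["background"]], nrow(pts))
  out[cls == 2L | rv_wall] <- spec$intensity[["myocardium"]]
  out[cls == 1L | cls == 3L] <- spec$intensity[["blood"]]
  out
}

#' Simulate a cine slice of the phantom
#'
#' Fills the plane's pixel grid with the intensity of the region containing
#' each pixel centre plus seeded Gaussian noise, and returns the ground-truth
#' label mask (0 background, 1 LV cavity, 2 LV myocardium, 3 RV cavity).
#'
#' @param spec a [phantom_spec()].
#' @param plane a `slice_plane` providing the pose and grid.
#' @param seed seed for the pixel noise (default derived from `spec$seed` and
#'   the plane id).
#' @return list with `plane` (pixels filled) and `mask` (integer matrix).
#' @export
slice_phantom <- function(spec, plane, seed = NULL) {
  imp <- phantom_implicits(spec)
  ij <- expand.grid(i = seq_len(plane$shape[1]) - 1L, j = seq_len(plane$shape[2]) - 1L)
  pts <- plane_to_world(plane, cbind(ij$j * plane$spacing[1], ij$i * plane$spacing[2]))
  inten <- .phantom_intensity_class(pts, spec, imp)
  cls <- .phantom_classify(pts, spec, imp)
  if (is.null(seed)) {
    seed <- spec$seed + if (is.null(plane$id)) 0L else sum(utf8ToInt(as.character(plane$id)))
  }
  if (spec$noise_sd > 0) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    set.seed(seed %% .Machine$integer.max)
    inten <- inten + rnorm(length(inten), 0, spec$noise_sd)
    if (!is.null(old)) assign(".Random.seed", old, globalenv())
  }
  img <- matrix(inten, plane$shape[1], plane$shape[2])
  mask <- matrix(cls, plane$shape[1], plane$shape[2])
  plane$pixels <- img
  list(plane = plane, mask = mask)
}

#' Analytic phantom contours on a slice
#'
#' Exact implicit-surface/plane intersection curves, Newton-refined onto the
#' zero level sets and resampled at the requested arc spacing, split into the
#' five anatomical labels. The septum is the part of the LV epicardial surface
#' that borders the RV cavity; the free-wall RV endocardium and the outer RV
#' wall (RV "epicardium") are the parts of the RV ellipsoids outside the LV.
#'
#' @param spec a [phantom_spec()].
#' @param plane a `slice_plane`.
#' @param spacing target arc spacing of contour points, mm.
#' @param grid_step sampling step of the in-plane marching grid, mm.
#' @return list of [labelled_contour()]s (possibly empty).
#' @export
analytic_contours <- function(spec, plane, spacing = 0.5, grid_step = 0.5) {
  imp <- phantom_implicits(spec)
  ext <- c((plane$shape[2] - 1) * plane$spacing[1],
           (plane$shape[1] - 1) * plane$spacing[2])
  xs <- seq(0, ext[1], by = grid_step)
  ys <- seq(0, ext[2], by = grid_step)
  u <- plane$u_axis; v <- plane$v_axis
  to3d <- function(xy) plane_to_world(plane, xy)
  grid_world <- function() {
    g <- expand.grid(x = xs, y = ys)
    to3d(cbind(g$x, g$y))
  }
  W <- grid_world()
  below <- function(p) p[, 3] <= spec$base_height + 1e-9
  dirs <- rbind(u, v)
  out <- list()
  add_curves <- function(fun, label_fun) {
    vals <- matrix(fun(W), length(xs), length(ys))
    cl <- contourLines(xs, ys, vals, levels = 0)
    for (curve in cl) {
      P <- cbind(curve$x, curve$y)
      if (nrow(P) < 3) next
      closed <- sqrt(sum((P[1, ] - P[nrow(P), ])^2)) < 1e-9
      if (closed) P <- P[-nrow(P), , drop = FALSE]
      P3 <- .project_implicit(to3d(P), fun, dirs = dirs)
      # base truncation + label mask, split into contiguous runs
      keep <- below(P3) & label_fun(P3)
      if (!any(keep)) next
      runs <- .mask_runs(keep, closed)
      for (rn in runs) {
        if (length(rn) < 3) next
        Q3 <- P3[rn, , drop = FALSE]
        run_closed <- closed && length(rn) == nrow(P3)
        Q3 <- .resample_polyline(Q3, spacing = spacing, closed = run_closed)
        Q3 <- .project_implicit(Q3, fun, dirs = dirs)
        if (nrow(Q3) < 3) next
        xy <- world_to_plane(plane, Q3)$xy
        out[[length(out) + 1L]] <<- list(points = xy, closed = run_closed)
      }
    }
  }
  res <- list()
  emit <- function(curves, label) {
    for (cv in curves)
      res[[length(res) + 1L]] <<- labelled_contour(label, cv$points, cv$closed,
                                                   slice_id = plane$id)
  }
  # LV endocardium
  out <- list()
  add_curves(imp$lv_endo, function(p) rep(TRUE, nrow(p)))
  emit(out, "LV_ENDO")
  # LV epicardial surface splits into free-wall epicardium and septum
  out <- list()
  add_curves(imp$lv_epi, function(p) imp$rv_epi(p) >= 0)
  emit(out, "LV_EPI")
  if (.has_rv(spec)) {
    out <- list()
    add_curves(imp$lv_epi, function(p) imp$rv_endo(p) <= 0)
    emit(out, "SEPTUM")
    out <- list()
    add_curves(imp$rv_endo, function(p) imp$lv_epi(p) >= 0)
    emit(out, "RV_ENDO")
    out <- list()
    add_curves(imp$rv_epi, function(p) imp$lv_epi(p) >= 0)
    emit(out, "RV_EPI")
  }
  res
}

# contiguous TRUE runs of a mask, wrapping around for closed curves
.mask_runs <- function(mask, closed) {
  n <- length(mask)
  if (all(mask)) return(list(seq_len(n)))
  idx <- seq_len(n)
  if (closed) {
    start <- which(!mask)[1]
    idx <- ((seq_len(n) + start - 2L) %% n) + 1L
    mask <- mask[idx]
  }
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- c(1, head(ends, -1) + 1)
  lapply(which(r$values), function(k) idx[starts[k]:ends[k]])
}

# ---------------------------------------------------------------------------
# Default acquisition layout

#' Default phantom acquisition planes
#'
#' A parallel short-axis stack plus radially fanned long-axis planes through
#' the LV long axis, emulating a standard cine protocol: 8 mm SAX intervals,
#' LAX planes separated by 45 degrees, 1.3672 mm in-plane resolution.
#'
#' @param spec a [phantom_spec()].
#' @param n_sax,sax_gap number and spacing (mm) of SAX planes.
#' @param n_lax number of radial LAX planes (at `180/n_lax` degree steps).
#' @param fov_n image grid size (pixels per side).
#' @param spacing in-plane pixel spacing, mm.
#' @return list of `slice_plane`s (without pixels), SAX first.
#' @export
default_study_planes <- function(spec, n_sax = 12, sax_gap = 8, n_lax = 4,
                                 fov_n = 128, spacing = 1.3672) {
  a_epi <- spec$lv_semi_axes + spec$lv_wall
  z0 <- -a_epi[3] + 4
  zs <- z0 + sax_gap * (seq_len(n_sax) - 1)
  half <- (fov_n - 1) / 2 * spacing
  planes <- list()
  fov_ctr <- c(max(0, spec$rv_offset[1] / 2), spec$rv_offset[2] / 2)
  for (k in seq_len(n_sax)) {
    ctr <- c(fov_ctr[1], fov_ctr[2], zs[k])
    planes[[length(planes) + 1L]] <-
      slice_plane(origin = ctr - half * c(1, 0, 0) - half * c(0, 1, 0),
                  u_axis = c(1, 0, 0), v_axis = c(0, 1, 0),
                  spacing = c(spacing, spacing), shape = c(fov_n, fov_n),
                  id = sprintf("SAX%02d", k))
  }
  c0 <- c(fov_ctr[1], fov_ctr[2], (spec$base_height - a_epi[3]) / 2)
  for (k in seq_len(n_lax)) {
    th <- (k - 1) * pi / n_lax
    u <- c(cos(th), sin(th), 0)
    v <- c(0, 0, 1)
    xc <- sum(c0 * u); yc <- sum(c0 * v)
    planes[[length(planes) + 1L]] <-
      slice_plane(origin = (xc - half) * u + (yc - half) * v,
                  u_axis = u, v_axis = v,
                  spacing = c(spacing, spacing), shape = c(fov_n, fov_n),
                  id = sprintf("LAX%d", k))
  }
  planes
}

#' Phantom cardiac-phase family
#'
#' A cyclic family of phantom specs whose LV cavity swells and shrinks, with
#' the maximum-volume (end-diastolic) member at `peak_phase`.
#'
#' @param spec base [phantom_spec()].
#' @param n_phases number of cardiac phases.
#' @param peak_phase 1-based index of the largest-cavity phase.
#' @param amplitude fractional in-plane semi-axis contraction at end-systole.
#' @return list of `phantom_spec`s.
#' @export
phantom_phase_family <- function(spec, n_phases = 8, peak_phase = 1, amplitude = 0.2) {
  lapply(seq_len(n_phases), function(p) {
    s <- 1 - amplitude * (1 - cos(2 * pi * (p - peak_phase) / n_phases)) / 2
    out <- spec
    out$lv_semi_axes <- spec$lv_semi_axes * c(s, s, sqrt(s))
    out
  })
}

# ---------------------------------------------------------------------------
# Misalignment injection

#' Inject seeded per-slice rigid misalignments
#'
#' Each slice pose is perturbed by an independent uniform draw: in-plane
#' translations `tx, ty`, rotation `gamma` about the slice normal, and
#' optionally a through-plane shift `tz`. The exact injected parameters are
#' returned so the inverse restores the original poses.
#'
#' @param planes list of `slice_plane`s.
#' @param ranges list with elements `tx`, `ty` (mm), `gamma` (degrees), each a
#'   length-2 `c(lo, hi)` bound, and optionally `tz` (mm).
#' @param seed integer seed; draws are reproducible bit-identically.
#' @return list with `planes` (perturbed), `truth` (list of `rigid_params`),
#'   `ranges` and `seed`.
#' @export
inject_misalignment <- function(planes,
                                ranges = list(tx = c(-5, 5), ty = c(-5, 5),
                                              gamma = c(-7, 7)),
                                seed = 1L) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  draw <- function(rg) if (is.null(rg)) 0 else runif(1, rg[1], rg[2])
  truth <- vector("list", length(planes))
  out <- vector("list", length(planes))
  for (k in seq_along(planes)) {
    tz <- draw(ranges$tz)
    th <- if (is.null(ranges$tz)) {
      rigid_inplane(tx = draw(ranges$tx), ty = draw(ranges$ty), gamma = draw(ranges$gamma))
    } else {
      rigid_params(tx = draw(ranges$tx), ty = draw(ranges$ty), tz = tz,
                   gamma = draw(ranges$gamma))
    }
    truth[[k]] <- th
    out[[k]] <- apply_rigid(planes[[k]], th)
  }
  if (!is.null(old)) assign(".Random.seed", old, globalenv())
  list(planes = out, truth = truth, ranges = ranges, seed = seed)
}
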