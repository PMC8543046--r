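# Forward anisotropic Eikonal activation-time simulation on a tetrahedral
# mesh: per-element conduction tensors from fiber/sheet/normal speeds with a
# fast isotropic endocardial layer, a Jacobi-style fast-iterative solver, and
# Pearson comparison against reference epicardial activation maps.

#' Conduction specification
#'
#' @param v_fiber,v_sheet,v_normal orthotropic myocardial conduction speeds,
#'   mm/ms.
#' @param v_endo isotropic speed of the fast endocardial layer, mm/ms.
#' @param endo_thickness endocardial layer thickness, mm.
#' @param roots integer vertex ids of the sites of first activation.
#' @param root_offsets activation time offsets per root, ms.
#' @param fibers optional m x 3 per-element unit fiber directions (a rule-based
#'   apex-to-base tangent field is generated when NULL).
#' @return object of class `conduction_spec`.
#' @export
conduction_spec <- function(v_fiber = 0.65, v_sheet = 0.40, v_normal = 0.25,
                            v_endo = 1.20, endo_thickness = 2,
                            roots = integer(0), root_offsets = NULL,
                            fibers = NULL) {
  stopifnot(v_fiber > 0, v_sheet > 0, v_normal > 0, v_endo > 0,
            endo_thickness >= 0)
  if (length(roots) == 0) stop("root set must be non-empty", call. = FALSE)
  if (is.null(root_offsets)) root_offsets <- rep(0, length(roots))
  stopifnot(length(root_offsets) == length(roots))
  structure(list(v_fiber = v_fiber, v_sheet = v_sheet, v_normal = v_normal,
                 v_endo = v_endo, endo_thickness = endo_thickness,
                 roots = as.integer(roots), root_offsets = as.numeric(root_offsets),
                 fibers = fibers),
            class = "conduction_spec")
}

# rule-based fiber field: the apex-to-base direction projected onto the local
# wall tangent plane (crude stand-in for a rule-based fiber model)
.default_fibers <- function(tmesh, axis = c(0, 0, 1)) {
  ctr <- (tmesh$vertices[tmesh$tets[, 1], ] + tmesh$vertices[tmesh$tets[, 2], ] +
            tmesh$vertices[tmesh$tets[, 3], ] + tmesh$vertices[tmesh$tets[, 4], ]) / 4
  surf <- tet_boundary_surface(tmesh)
  q <- point_to_mesh_distance(ctr, surf, details = TRUE)
  n <- q$nearest - ctr
  nl <- sqrt(rowSums(n^2))
  n <- n / pmax(nl, 1e-9)
  ax <- matrix(axis, nrow(ctr), 3, byrow = TRUE)
  f <- ax - n * rowSums(ax * n)
  fl <- sqrt(rowSums(f^2))
  deg <- fl < 1e-6
  if (any(deg)) {
    alt <- cbind(1, 0, 0) [rep(1, sum(deg)), , drop = FALSE]
    f[deg, ] <- alt - n[deg, , drop = FALSE] * rowSums(alt * n[deg, , drop = FALSE])
    fl[deg] <- sqrt(rowSums(f[deg, , drop = FALSE]^2))
  }
  f / pmax(fl, 1e-9)
}

#' Per-element conduction tensors
#'
#' Builds `M = v_f^2 f f' + v_s^2 s s' + v_n^2 n n'` from an orthonormal local
#' frame (fiber, sheet, sheet-normal); elements whose centroid lies within the
#' endocardial layer thickness of an endocardial surface vertex get the
#' isotropic `v_endo^2 I` tensor.
#'
#' @param tmesh a [tetra_mesh()].
#' @param spec a [conduction_spec()].
#' @param endo_vertices matrix of endocardial surface points (the fast layer
#'   seeds), or NULL for none.
#' @return m x 6 matrix of symmetric tensors (xx, xy, xz, yy, yz, zz), attached
#'   attribute `endo_layer` (logical per element).
#' @export
build_speed_tensors <- function(tmesh, spec, endo_vertices = NULL) {
  m <- nrow(tmesh$tets)
  f <- spec$fibers
  if (is.null(f)) f <- .default_fibers(tmesh)
  f <- as.matrix(f)
  if (nrow(f) != m) stop("fiber field must have one row per element", call. = FALSE)
  fl <- sqrt(rowSums(f^2))
  if (any(fl < 1e-9)) stop("zero fiber vector", call. = FALSE)
  f <- f / fl
  # sheet direction: any unit vector orthogonal to f (wall-normal-ish), then
  # n = f x s completes the frame
  ref <- matrix(c(0, 0, 1), m, 3, byrow = TRUE)
  par <- abs(rowSums(f * ref)) > 0.95
  ref[par, ] <- matrix(c(1, 0, 0), sum(par), 3, byrow = TRUE)
  s <- ref - f * rowSums(ref * f)
  s <- s / sqrt(rowSums(s^2))
  n <- cbind(f[, 2] * s[, 3] - f[, 3] * s[, 2],
             f[, 3] * s[, 1] - f[, 1] * s[, 3],
             f[, 1] * s[, 2] - f[, 2] * s[, 1])
  tens <- function(v, d) {
    cbind(v^2 * d[, 1]^2, v^2 * d[, 1] * d[, 2], v^2 * d[, 1] * d[, 3],
          v^2 * d[, 2]^2, v^2 * d[, 2] * d[, 3], v^2 * d[, 3]^2)
  }
  M <- tens(spec$v_fiber, f) + tens(spec$v_sheet, s) + tens(spec$v_normal, n)
  endo_layer <- rep(FALSE, m)
  if (!is.null(endo_vertices) && nrow(rbind(endo_vertices)) > 0 &&
      spec$endo_thickness > 0) {
    ctr <- (tmesh$vertices[tmesh$tets[, 1], ] + tmesh$vertices[tmesh$tets[, 2], ] +
              tmesh$vertices[tmesh$tets[, 3], ] + tmesh$vertices[tmesh$tets[, 4], ]) / 4
    ev <- rbind(endo_vertices)
    # nearest endo point distance (coarse chunked search)
    dmin <- rep(Inf, m)
    step <- 2000L
    for (s0 in seq(1, nrow(ev), by = step)) {
      block <- ev[s0:min(nrow(ev), s0 + step - 1L), , drop = FALSE]
      d2 <- outer(rowSums(ctr^2), rep(1, nrow(block))) +
        outer(rep(1, m), rowSums(block^2)) - 2 * ctr %*% t(block)
      dmin <- pmin(dmin, sqrt(pmax(apply(d2, 1, min), 0)))
    }
    endo_layer <- dmin <= spec$endo_thickness
    iso <- spec$v_endo^2
    M[endo_layer, ] <- matrix(c(iso, 0, 0, iso, 0, iso), sum(endo_layer), 6,
                              byrow = TRUE)
  }
  attr(M, "endo_layer") <- endo_layer
  M
}

# invert m x 6 packed symmetric tensors
.invert_tensors <- function(M) {
  a <- M[, 1]; b <- M[, 2]; c <- M[, 3]; d <- M[, 4]; e <- M[, 5]; f <- M[, 6]
  det <- a * (d * f - e * e) - b * (b * f - e * c) + c * (b * e - d * c)
  if (any(det <= 0)) stop("conduction tensors must be positive definite", call. = FALSE)
  cbind((d * f - e * e) / det,
        (c * e - b * f) / det,
        (b * e - c * d) / det,
        (a * f - c * c) / det,
        (b * c - a * e) / det,
        (a * d - b * b) / det)
}

#' Solve the anisotropic Eikonal equation on a tetrahedral mesh
#'
#' Jacobi-style fast-iterative local solver: each vertex repeatedly takes the
#' minimum arrival time over its incident elements, where the arrival within
#' one element is the linear-wavefront time from the opposite face under the
#' metric `M^{-1}` (segment travel time `sqrt(e' M^{-1} e)`). Vertex and edge
#' relaxations bound the solution by the edge-graph shortest path. Root
#' vertices keep their offsets exactly; the result is independent of vertex
#' ordering.
#'
#' @param tmesh a [tetra_mesh()].
#' @param tensors m x 6 conduction tensors from [build_speed_tensors()], or a
#'   single speed (mm/ms) for isotropic conduction.
#' @param roots integer vertex ids (or a [conduction_spec()]).
#' @param offsets per-root activation offsets, ms.
#' @param tol convergence threshold, ms.
#' @param max_sweeps iteration cap.
#' @param seed_radius radius of the analytically seeded neighbourhood around
#'   each root (default 3 median edge lengths; 0 disables).
#' @return object of class `activation_map`: `times` (ms per vertex, NA where
#'   unreached), `reached`, `roots`.
#' @export
solve_eikonal <- function(tmesh, tensors, roots, offsets = NULL,
                          tol = 1e-6, max_sweeps = 5000, seed_radius = NULL) {
  if (inherits(roots, "conduction_spec")) {
    offsets <- roots$root_offsets
    roots <- roots$roots
  }
  if (is.null(offsets)) offsets <- rep(0, length(roots))
  m <- nrow(tmesh$tets)
  if (length(tensors) == 1) {
    v2 <- as.numeric(tensors)^2
    tensors <- matrix(c(v2, 0, 0, v2, 0, v2), m, 6, byrow = TRUE)
  }
  Qinv <- .invert_tensors(tensors)
  # near-field seeding: vertices close to a root start from the straight-line
  # travel time under the root's local metric (upper bounds, still relaxed by
  # the sweeps) - removes the first-order error at the wavefront origin
  if (is.null(seed_radius)) {
    el <- sqrt(rowSums((tmesh$vertices[tmesh$tets[, 1], ] -
                          tmesh$vertices[tmesh$tets[, 2], ])^2))
    seed_radius <- 3 * median(el)
  }
  init <- rep(Inf, nrow(tmesh$vertices))
  if (seed_radius > 0) {
    for (r in seq_along(roots)) {
      rv <- roots[r]
      ktet <- which(rowSums(tmesh$tets == rv) > 0)[1]
      Q <- Qinv[ktet, ]
      d <- sweep(tmesh$vertices, 2, tmesh$vertices[rv, ])
      near <- which(rowSums(d^2) <= seed_radius^2)
      dn <- d[near, , drop = FALSE]
      tt <- sqrt(Q[1] * dn[, 1]^2 + Q[4] * dn[, 2]^2 + Q[6] * dn[, 3]^2 +
                   2 * (Q[2] * dn[, 1] * dn[, 2] + Q[3] * dn[, 1] * dn[, 3] +
                          Q[5] * dn[, 2] * dn[, 3]))
      init[near] <- pmin(init[near], offsets[r] + tt)
    }
  }
  times <- cpp_solve_eikonal(tmesh$vertices, tmesh$tets, Qinv,
                             as.integer(roots), as.numeric(offsets),
                             tol, as.integer(max_sweeps), init)
  reached <- !is.na(times)
  if (!all(reached))
    warning(sprintf("%d vertices unreached (disconnected from all roots)",
                    sum(!reached)))
  structure(list(times = as.numeric(times), reached = reached,
                 roots = as.integer(roots)),
            class = "activation_map")
}

#' @export
print.activation_map <- function(x, ...) {
  cat(sprintf("<activation_map: %d vertices, %d roots, range %.2f-%.2f ms>\n",
              length(x$times), length(x$roots),
              min(x$times, na.rm = TRUE), max(x$times, na.rm = TRUE)))
  invisible(x)
}

#' Pair a reference epicardial map with mesh vertices
#'
#' Nearest-neighbour pairing of each reference surface point with an
#' epicardial mesh vertex; ties resolve to the lowest vertex index, and an
#' exclusion mask (e.g. valve-plane artefacts) drops reference points.
#'
#' @param map an [solve_eikonal()] result on `tmesh`.
#' @param tmesh the [tetra_mesh()].
#' @param reference_points k x 3 matrix of reference surface points.
#' @param reference_values k activation times.
#' @param epi_vertex_ids vertex ids considered epicardial (default: all
#'   boundary vertices).
#' @param exclude logical mask of reference points to drop.
#' @return data.frame with `reference`, `simulated`, `vertex`, `distance`.
#' @export
map_to_epicardium <- function(map, tmesh, reference_points, reference_values,
                              epi_vertex_ids = NULL, exclude = NULL) {
  reference_points <- rbind(reference_points)
  if (nrow(reference_points) == 0) stop("empty reference map", call. = FALSE)
  stopifnot(nrow(reference_points) == length(reference_values))
  if (!is.null(exclude)) {
    reference_points <- reference_points[!exclude, , drop = FALSE]
    reference_values <- reference_values[!exclude]
  }
  if (is.null(epi_vertex_ids)) {
    bnd <- cpp_tet_boundary(tmesh$tets, nrow(tmesh$vertices))
    epi_vertex_ids <- sort(unique(as.vector(bnd)))
  }
  EV <- tmesh$vertices[epi_vertex_ids, , drop = FALSE]
  d2 <- outer(rowSums(reference_points^2), rep(1, nrow(EV))) +
    outer(rep(1, nrow(reference_points)), rowSums(EV^2)) -
    2 * reference_points %*% t(EV)
  nn <- apply(d2, 1, which.min)  # which.min takes the first (lowest index) tie
  data.frame(reference = reference_values,
             simulated = map$times[epi_vertex_ids[nn]],
             vertex = epi_vertex_ids[nn],
             distance = sqrt(pmax(d2[cbind(seq_along(nn), nn)], 0)))
}

#' Pearson correlation of paired activation times
#'
#' @param paired data.frame from [map_to_epicardium()], or two numeric vectors.
#' @param simulated second vector when `paired` is numeric.
#' @return Pearson r in `[-1, 1]`.
#' @export
activation_correlation <- function(paired, simulated = NULL) {
  if (is.data.frame(paired)) {
    a <- paired$reference; b <- paired$simulated
  } else {
    a <- paired; b <- simulated
  }
  ok <- !is.na(a) & !is.na(b)
  a <- a[ok]; b <- b[ok]
  if (length(a) < 3) stop("need at least 3 pairs", call. = FALSE)
  if (sd(a) == 0 || sd(b) == 0) stop("zero variance in activation times", call. = FALSE)
  cor(a, b)
}

#' Convenience grid calibration of conduction parameters
#'
#' Sweeps candidate fiber and endocardial speeds (and optionally root choices)
#' and returns the combination maximising the Pearson correlation against a
#' reference epicardial map. A simple forward-simulation sweep, not an inverse
#' inference procedure.
#'
#' @param tmesh a [tetra_mesh()].
#' @param reference_points,reference_values the reference epicardial map.
#' @param v_fiber_grid,v_endo_grid candidate speeds, mm/ms.
#' @param root_choices list of candidate root vertex sets.
#' @param spec base [conduction_spec()] supplying the remaining parameters.
#' @param endo_vertices endocardial layer seed points.
#' @return list with `best` (spec of the winning combination), `r`, and the
#'   full sweep `table`.
#' @export
calibrate_conduction <- function(tmesh, reference_points, reference_values,
                                 v_fiber_grid = c(0.5, 0.65, 0.8),
                                 v_endo_grid = c(1.0, 1.5),
                                 root_choices = NULL, spec = NULL,
                                 endo_vertices = NULL) {
  if (is.null(spec))
    spec <- conduction_spec(roots = 1L)
  if (is.null(root_choices)) root_choices <- list(spec$roots)
  rows <- list()
  best <- NULL
  for (vf in v_fiber_grid) for (ve in v_endo_grid) for (ri in seq_along(root_choices)) {
    sp <- conduction_spec(v_fiber = vf, v_sheet = spec$v_sheet * vf / spec$v_fiber,
                          v_normal = spec$v_normal * vf / spec$v_fiber,
                          v_endo = ve, endo_thickness = spec$endo_thickness,
                          roots = root_choices[[ri]], fibers = spec$fibers)
    M <- build_speed_tensors(tmesh, sp, endo_vertices)
    am <- solve_eikonal(tmesh, M, sp)
    paired <- map_to_epicardium(am, tmesh, reference_points, reference_values)
    r <- activation_correlation(paired)
    rows[[length(rows) + 1L]] <- data.frame(v_fiber = vf, v_endo = ve,
                                            root_set = ri, r = r)
    if (is.null(best) || r > best$r) best <- list(spec = sp, r = r)
  }
  list(best = best$spec, r = best$r, table = do.call(rbind, rows))
}

#' Read a conduction specification from YAML
#'
#' Fields: `v_fiber`, `v_sheet`, `v_normal`, `v_endo` (mm/ms),
#' `endo_thickness` (mm), `roots` (vertex ids), optional `root_offsets` (ms).
#'
#' @param path YAML file.
#' @return a [conduction_spec()].
#' @export
read_conduction_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  conduction_spec(v_fiber = y$v_fiber %||% 0.65,
                  v_sheet = y$v_sheet %||% 0.40,
                  v_normal = y$v_normal %||% 0.25,
                  v_endo = y$v_endo %||% 1.20,
                  endo_thickness = y$endo_thickness %||% 2,
                  roots = as.integer(unlist(y$roots)),
                  root_offsets = if (is.null(y$root_offsets)) NULL
                                 else as.numeric(unlist(y$root_offsets)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
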