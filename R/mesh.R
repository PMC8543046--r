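# Triangle surface meshes: containers, BVH-accelerated point queries,
# watertightness audits, smoothing, plane cross-sections and clipping.

#' Construct a triangle surface mesh
#'
#' @param vertices n x 3 matrix, mm.
#' @param triangles m x 3 integer matrix of 1-based vertex indices.
#' @param label one of `LV_ENDO`, `RV_ENDO`, `EPI`, `BIVENTRICULAR`.
#' @param check audit index ranges and degenerate triangles (area > 1e-9 mm^2).
#' @return object of class `surface_mesh`.
#' @export
surface_mesh <- function(vertices, triangles, label = "BIVENTRICULAR", check = TRUE) {
  vertices <- as.matrix(vertices)
  triangles <- matrix(as.integer(as.matrix(triangles)), ncol = 3)
  label <- match.arg(label, .surface_labels)
  if (ncol(vertices) != 3L) stop("vertices must be n x 3", call. = FALSE)
  if (check) {
    if (nrow(triangles) > 0 &&
        (min(triangles) < 1L || max(triangles) > nrow(vertices)))
      stop("triangle indices out of range", call. = FALSE)
    if (nrow(triangles) > 0) {
      a <- .tri_areas(vertices, triangles)
      if (any(a <= 1e-9))
        stop(sprintf("%d degenerate triangles (area <= 1e-9 mm^2)", sum(a <= 1e-9)),
             call. = FALSE)
    }
  }
  structure(list(vertices = unname(vertices), triangles = unname(triangles),
                 label = label),
            class = "surface_mesh")
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat(sprintf("<surface_mesh %s: %d vertices, %d triangles>\n",
              x$label, nrow(x$vertices), nrow(x$triangles)))
  invisible(x)
}

.tri_areas <- function(V, F) {
  e1 <- V[F[, 2], , drop = FALSE] - V[F[, 1], , drop = FALSE]
  e2 <- V[F[, 3], , drop = FALSE] - V[F[, 1], , drop = FALSE]
  cx <- e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2]
  cy <- e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3]
  cz <- e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1]
  0.5 * sqrt(cx^2 + cy^2 + cz^2)
}

#' Total surface area (mm^2)
#' @param mesh a `surface_mesh`.
#' @export
mesh_area <- function(mesh) sum(.tri_areas(mesh$vertices, mesh$triangles))

#' Enclosed volume of a closed oriented mesh (mm^3)
#'
#' Signed divergence-theorem sum; the absolute value is returned so the
#' result does not depend on global orientation.
#' @param mesh a `surface_mesh`.
#' @export
mesh_volume <- function(mesh) {
  V <- mesh$vertices; F <- mesh$triangles
  a <- V[F[, 1], , drop = FALSE]
  b <- V[F[, 2], , drop = FALSE]
  cc <- V[F[, 3], , drop = FALSE]
  s <- a[, 1] * (b[, 2] * cc[, 3] - b[, 3] * cc[, 2]) -
       a[, 2] * (b[, 1] * cc[, 3] - b[, 3] * cc[, 1]) +
       a[, 3] * (b[, 1] * cc[, 2] - b[, 2] * cc[, 1])
  abs(sum(s)) / 6
}

.mesh_edges <- function(triangles) {
  e <- rbind(triangles[, 1:2, drop = FALSE],
             triangles[, 2:3, drop = FALSE],
             triangles[, c(3, 1), drop = FALSE])
  cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
}

#' Boundary edges of a mesh
#' @param mesh a `surface_mesh`.
#' @return k x 2 matrix of vertex index pairs appearing in exactly one triangle.
#' @export
mesh_boundary_edges <- function(mesh) {
  e <- .mesh_edges(mesh$triangles)
  key <- paste(e[, 1], e[, 2])
  tab <- table(key)
  bkey <- names(tab)[tab == 1L]
  e[match(bkey, key), , drop = FALSE]
}

#' Is a mesh watertight?
#'
#' TRUE when every edge is shared by exactly two triangles.
#' @param mesh a `surface_mesh`.
#' @export
mesh_is_watertight <- function(mesh) {
  e <- .mesh_edges(mesh$triangles)
  tab <- table(paste(e[, 1], e[, 2]))
  all(tab == 2L)
}

#' Ordered boundary loops
#' @param mesh a `surface_mesh`.
#' @return list of integer vectors, each an ordered closed loop of vertex ids.
#' @export
mesh_boundary_loops <- function(mesh) {
  be <- mesh_boundary_edges(mesh)
  if (nrow(be) == 0) return(list())
  nxt <- split(c(be[, 2], be[, 1]), c(be[, 1], be[, 2]))
  used <- new.env(parent = emptyenv())
  ekey <- function(a, b) paste(min(a, b), max(a, b))
  loops <- list()
  for (k in seq_len(nrow(be))) {
    if (!is.null(used[[ekey(be[k, 1], be[k, 2])]])) next
    loop <- c(be[k, 1], be[k, 2])
    used[[ekey(be[k, 1], be[k, 2])]] <- TRUE
    repeat {
      cur <- loop[length(loop)]
      cand <- nxt[[as.character(cur)]]
      cand <- cand[vapply(cand, function(x) is.null(used[[ekey(cur, x)]]), logical(1))]
      if (length(cand) == 0) break
      nx <- cand[1]
      used[[ekey(cur, nx)]] <- TRUE
      if (nx == loop[1]) break
      loop <- c(loop, nx)
    }
    loops[[length(loops) + 1L]] <- loop
  }
  loops
}

# ---------------------------------------------------------------------------
# BVH acceleration

#' Build a reusable spatial index for a mesh
#'
#' @param mesh a `surface_mesh`.
#' @return object of class `mesh_bvh` wrapping the accelerated structure.
#' @export
mesh_bvh <- function(mesh) {
  if (nrow(mesh$triangles) == 0) stop("empty mesh", call. = FALSE)
  structure(list(ptr = cpp_bvh_build(mesh$vertices, mesh$triangles),
                 mesh = mesh),
            class = "mesh_bvh")
}

.as_bvh <- function(x) {
  if (inherits(x, "mesh_bvh")) x else mesh_bvh(x)
}

#' Exact point-to-surface distances
#'
#' Minimum Euclidean distance from each query point to the closest triangle of
#' the mesh (not merely the closest vertex).
#'
#' @param points n x 3 matrix of query points.
#' @param mesh a `surface_mesh` or a prebuilt [mesh_bvh()].
#' @param details return nearest points and triangle ids as well.
#' @return numeric vector of distances (mm), or a list when `details = TRUE`.
#' @export
point_to_mesh_distance <- function(points, mesh, details = FALSE) {
  bvh <- .as_bvh(mesh)
  points <- rbind(points)
  res <- cpp_bvh_query(bvh$ptr, points)
  if (details) res else as.numeric(res$distance)
}

#' Inside test by ray-casting parity
#'
#' @param points n x 3 matrix.
#' @param mesh a closed `surface_mesh` or [mesh_bvh()].
#' @return logical vector.
#' @export
mesh_inside <- function(points, mesh) {
  bvh <- .as_bvh(mesh)
  as.logical(cpp_bvh_inside(bvh$ptr, rbind(points)))
}

#' Signed distance to a closed mesh (negative inside)
#' @param points n x 3 matrix.
#' @param mesh a closed `surface_mesh` or [mesh_bvh()].
#' @export
mesh_signed_distance <- function(points, mesh) {
  bvh <- .as_bvh(mesh)
  d <- point_to_mesh_distance(points, bvh)
  inside <- mesh_inside(points, bvh)
  ifelse(inside, -d, d)
}

#' Count crossing triangle pairs between two meshes
#' @param a,b `surface_mesh`es.
#' @return integer count of genuinely straddling triangle pairs.
#' @export
mesh_crossings <- function(a, b) {
  cpp_tri_tri_crossings(a$vertices, a$triangles, b$vertices, b$triangles)
}

# ---------------------------------------------------------------------------

#' Laplacian smoothing of mesh vertices
#'
#' One or more passes of `v <- (1 - lambda) v + lambda mean(neighbours)`.
#' Boundary vertices (on boundary edges) are kept fixed.
#'
#' @param mesh a `surface_mesh`.
#' @param lambda blending weight in (0, 1].
#' @param iterations number of passes.
#' @param fix_boundary keep boundary-loop vertices in place.
#' @return smoothed `surface_mesh`.
#' @export
laplacian_smooth <- function(mesh, lambda = 0.2, iterations = 1, fix_boundary = TRUE) {
  V <- mesh$vertices
  e <- .mesh_edges(mesh$triangles)
  adj <- rbind(e, e[, 2:1, drop = FALSE])
  fixed <- rep(FALSE, nrow(V))
  if (fix_boundary) {
    be <- mesh_boundary_edges(mesh)
    fixed[unique(as.vector(be))] <- TRUE
  }
  ord <- sort(unique(adj[, 1]))
  cnt <- as.numeric(table(factor(adj[, 1], levels = ord)))
  for (it in seq_len(iterations)) {
    s <- rowsum(V[adj[, 2], , drop = FALSE], adj[, 1])
    mean_nb <- s / cnt
    move <- !fixed & seq_len(nrow(V)) %in% ord
    V[move, ] <- (1 - lambda) * V[move, , drop = FALSE] +
      lambda * mean_nb[match(which(move), ord), , drop = FALSE]
  }
  surface_mesh(V, mesh$triangles, mesh$label, check = FALSE)
}

#' Cross-section of a mesh with a plane
#'
#' Intersects every triangle with the plane and chains the resulting segments
#' into polylines.
#'
#' @param mesh a `surface_mesh`.
#' @param plane a `slice_plane` (its infinite plane is used).
#' @return list of polylines; each is a list with `points` (k x 3, on the
#'   plane) and `triangles` (contributing triangle ids), `closed` flag.
#' @export
mesh_cross_section <- function(mesh, plane) {
  n <- plane_normal(plane)
  d <- as.numeric(mesh$vertices %*% n) - sum(n * plane$origin)
  F <- mesh$triangles
  s <- matrix(d[F], ncol = 3)
  hit <- which(!(rowSums(s > 0) == 3 | rowSums(s < 0) == 3))
  if (length(hit) == 0) return(list())
  segs <- vector("list", length(hit))
  keyfun <- function(a, b, ta) {
    if (ta == 0) return(sprintf("v%d", a))
    sprintf("e%d_%d", min(a, b), max(a, b))
  }
  pts_env <- new.env(parent = emptyenv())
  seg_list <- list()
  for (idx in seq_along(hit)) {
    k <- hit[idx]
    vid <- F[k, ]
    dv <- d[vid]
    ends <- list()
    for (e in list(c(1, 2), c(2, 3), c(3, 1))) {
      a <- vid[e[1]]; b <- vid[e[2]]
      da <- dv[e[1]]; db <- dv[e[2]]
      if (da == 0 && db == 0) next
      if (da == 0) {
        ends[[length(ends) + 1L]] <- list(key = sprintf("v%d", a), p = mesh$vertices[a, ])
      } else if ((da > 0) != (db > 0)) {
        t <- da / (da - db)
        p <- mesh$vertices[a, ] + t * (mesh$vertices[b, ] - mesh$vertices[a, ])
        ends[[length(ends) + 1L]] <- list(key = sprintf("e%d_%d", min(a, b), max(a, b)), p = p)
      }
    }
    keys <- vapply(ends, `[[`, character(1), "key")
    ends <- ends[!duplicated(keys)]
    if (length(ends) == 2)
      seg_list[[length(seg_list) + 1L]] <- list(k = k, a = ends[[1]], b = ends[[2]])
  }
  if (length(seg_list) == 0) return(list())
  # chain segments by shared endpoint keys
  akeys <- vapply(seg_list, function(s) s$a$key, character(1))
  bkeys <- vapply(seg_list, function(s) s$b$key, character(1))
  used <- rep(FALSE, length(seg_list))
  out <- list()
  for (start in seq_along(seg_list)) {
    if (used[start]) next
    used[start] <- TRUE
    chain_keys <- c(akeys[start], bkeys[start])
    chain_pts <- rbind(seg_list[[start]]$a$p, seg_list[[start]]$b$p)
    chain_tris <- seg_list[[start]]$k
    repeat {
      tailk <- chain_keys[length(chain_keys)]
      j <- which(!used & (akeys == tailk | bkeys == tailk))[1]
      if (is.na(j)) {
        # try extending at the head by reversing
        headk <- chain_keys[1]
        j <- which(!used & (akeys == headk | bkeys == headk))[1]
        if (is.na(j)) break
        chain_keys <- rev(chain_keys)
        chain_pts <- chain_pts[rev(seq_len(nrow(chain_pts))), , drop = FALSE]
        next
      }
      used[j] <- TRUE
      s <- seg_list[[j]]
      if (akeys[j] == chain_keys[length(chain_keys)]) {
        chain_keys <- c(chain_keys, bkeys[j])
        chain_pts <- rbind(chain_pts, s$b$p)
      } else {
        chain_keys <- c(chain_keys, akeys[j])
        chain_pts <- rbind(chain_pts, s$a$p)
      }
      chain_tris <- c(chain_tris, s$k)
      if (chain_keys[length(chain_keys)] == chain_keys[1]) break
    }
    closed <- chain_keys[length(chain_keys)] == chain_keys[1]
    if (closed) chain_pts <- chain_pts[-nrow(chain_pts), , drop = FALSE]
    out[[length(out) + 1L]] <- list(points = chain_pts, triangles = chain_tris,
                                    closed = closed)
  }
  out
}

#' Clip a mesh below a plane
#'
#' Keeps the part with `normal . (x - point) <= 0`, cutting crossing triangles
#' along the plane.
#'
#' @param mesh a `surface_mesh`.
#' @param point a point on the clipping plane.
#' @param normal plane normal; the positive side is removed.
#' @return clipped `surface_mesh` (cut vertices lie exactly on the plane).
#' @export
mesh_clip_plane <- function(mesh, point, normal) {
  n <- .unit(as.numeric(normal))
  V <- mesh$vertices
  d <- as.numeric(V %*% n) - sum(n * as.numeric(point))
  d[abs(d) < 1e-9] <- 0
  F <- mesh$triangles
  newv <- list()
  cutkey <- new.env(parent = emptyenv())
  nv0 <- nrow(V)
  cut <- function(a, b) {
    if (d[a] == 0) return(a)
    if (d[b] == 0) return(b)
    key <- paste(min(a, b), max(a, b))
    id <- cutkey[[key]]
    if (!is.null(id)) return(id)
    t <- d[a] / (d[a] - d[b])
    p <- V[a, ] + t * (V[b, ] - V[a, ])
    newv[[length(newv) + 1L]] <<- p
    id <- nv0 + length(newv)
    cutkey[[key]] <- id
    id
  }
  tris <- list()
  for (k in seq_len(nrow(F))) {
    vid <- F[k, ]
    dv <- d[vid]
    keep <- dv <= 0
    nk <- sum(keep)
    if (nk == 0) next
    if (nk == 3) { tris[[length(tris) + 1L]] <- vid; next }
    ins <- vid[keep]; outs <- vid[!keep]
    # preserve cyclic order for orientation
    emit3 <- function(a, b, cc) {
      if (a != b && b != cc && a != cc)
        tris[[length(tris) + 1L]] <<- c(a, b, cc)
    }
    if (nk == 1) {
      p <- ins[1]
      pos <- which(vid == p)
      nxt <- vid[(pos %% 3) + 1]; prv <- vid[((pos + 1) %% 3) + 1]
      c1 <- cut(p, nxt); c2 <- cut(p, prv)
      emit3(p, c1, c2)
    } else {
      o <- outs[1]
      pos <- which(vid == o)
      nxt <- vid[(pos %% 3) + 1]; prv <- vid[((pos + 1) %% 3) + 1]
      c1 <- cut(prv, o); c2 <- cut(nxt, o)
      emit3(prv, nxt, c2)
      if (c2 != nxt) emit3(prv, c2, c1) else emit3(prv, nxt, c1)
    }
  }
  V2 <- rbind(V, do.call(rbind, newv))
  T2 <- do.call(rbind, tris)
  if (is.null(T2)) stop("clip removed the entire mesh", call. = FALSE)
  keepv <- sort(unique(as.vector(T2)))
  remap <- integer(nrow(V2)); remap[keepv] <- seq_along(keepv)
  surface_mesh(V2[keepv, , drop = FALSE],
               matrix(remap[T2], ncol = 3), mesh$label, check = FALSE)
}

# consistent outward orientation for a closed mesh: flip all triangles if the
# signed volume is negative
.orient_outward <- function(mesh) {
  V <- mesh$vertices; F <- mesh$triangles
  a <- V[F[, 1], , drop = FALSE]; b <- V[F[, 2], , drop = FALSE]; cc <- V[F[, 3], , drop = FALSE]
  s <- sum(a[, 1] * (b[, 2] * cc[, 3] - b[, 3] * cc[, 2]) -
           a[, 2] * (b[, 1] * cc[, 3] - b[, 3] * cc[, 1]) +
           a[, 3] * (b[, 1] * cc[, 2] - b[, 2] * cc[, 1]))
  if (s < 0) mesh$triangles <- mesh$triangles[, c(1, 3, 2), drop = FALSE]
  mesh
}

#' Is a mesh closed?
#'
#' TRUE when every edge appears in an even number of triangles: the surface
#' bounds a volume, though it may pinch (non-manifold contact) where opposite
#' walls meet at mesh resolution. [mesh_is_watertight()] is the strict
#' (exactly two triangles per edge) test.
#' @param mesh a `surface_mesh`.
#' @export
mesh_is_closed <- function(mesh) {
  e <- .mesh_edges(mesh$triangles)
  tab <- table(paste(e[, 1], e[, 2]))
  all(tab %% 2L == 0L)
}
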