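# Small 2D polyline/polygon helpers shared by the phantom, contour extraction
# and basal stitching code.

# cumulative arc length of an n x d polyline
.arc_length <- function(P, closed = FALSE) {
  if (closed) P <- rbind(P, P[1, ])
  seg <- sqrt(rowSums((P[-1, , drop = FALSE] - P[-nrow(P), , drop = FALSE])^2))
  c(0, cumsum(seg))
}

# resample a polyline at n points (or at target arc spacing) by linear
# interpolation; closed polylines return n points without repeating the start
.resample_polyline <- function(P, n = NULL, spacing = NULL, closed = FALSE) {
  s <- .arc_length(P, closed)
  total <- s[length(s)]
  if (total <= 0) return(P[1, , drop = FALSE])
  if (is.null(n)) n <- max(3L, ceiling(total / spacing) + if (closed) 0L else 1L)
  Q <- if (closed) rbind(P, P[1, ]) else P
  at <- if (closed) seq(0, total, length.out = n + 1L)[-(n + 1L)]
        else seq(0, total, length.out = n)
  out <- matrix(0, length(at), ncol(P))
  for (d in seq_len(ncol(P)))
    out[, d] <- approx(s, Q[, d], xout = at, rule = 2, ties = "ordered")$y
  out
}

# signed area of a 2D polygon (positive = counter-clockwise)
.polygon_area2 <- function(P) {
  n <- nrow(P)
  j <- c(2:n, 1)
  sum(P[, 1] * P[j, 2] - P[j, 1] * P[, 2]) / 2
}

.point_in_polygon <- function(pt, P) {
  # even-odd rule
  n <- nrow(P)
  j <- c(2:n, 1)
  x <- pt[1]; y <- pt[2]
  crossings <- (P[, 2] > y) != (P[j, 2] > y)
  xi <- P[, 1] + (y - P[, 2]) / (P[j, 2] - P[, 2]) * (P[j, 1] - P[, 1])
  sum(crossings & xi > x, na.rm = TRUE) %% 2 == 1
}

# Ear-clipping triangulation of a simple 2D polygon (indices into P).
# Returns a k x 3 matrix of row indices. Robust enough for the smooth,
# near-convex cross-sections this package produces.
.ear_clip <- function(P) {
  n <- nrow(P)
  if (n < 3) return(matrix(integer(0), 0, 3))
  idx <- seq_len(n)
  if (.polygon_area2(P) < 0) idx <- rev(idx)
  tris <- matrix(integer(0), 0, 3)
  guard <- 0L
  while (length(idx) > 3L && guard < 10L * n) {
    guard <- guard + 1L
    m <- length(idx)
    clipped <- FALSE
    for (k in seq_len(m)) {
      a <- idx[(k - 2L) %% m + 1L]
      b <- idx[(k - 1L) %% m + 1L]
      cc <- idx[k %% m + 1L]
      v1 <- P[b, ] - P[a, ]; v2 <- P[cc, ] - P[a, ]
      cr <- v1[1] * v2[2] - v1[2] * v2[1]
      if (cr <= 1e-12) next  # reflex or degenerate corner
      # no other polygon vertex inside the candidate ear
      tri <- P[c(a, b, cc), , drop = FALSE]
      others <- setdiff(idx, c(a, b, cc))
      bad <- FALSE
      if (length(others)) {
        w <- P[others, , drop = FALSE]
        # ignore vertices coinciding with an ear corner (bridge duplicates)
        dup <- rep(FALSE, nrow(w))
        for (cnr in 1:3)
          dup <- dup | (abs(w[, 1] - tri[cnr, 1]) < 1e-9 & abs(w[, 2] - tri[cnr, 2]) < 1e-9)
        d1 <- (tri[2, 1] - tri[1, 1]) * (w[, 2] - tri[1, 2]) - (tri[2, 2] - tri[1, 2]) * (w[, 1] - tri[1, 1])
        d2 <- (tri[3, 1] - tri[2, 1]) * (w[, 2] - tri[2, 2]) - (tri[3, 2] - tri[2, 2]) * (w[, 1] - tri[2, 1])
        d3 <- (tri[1, 1] - tri[3, 1]) * (w[, 2] - tri[3, 2]) - (tri[1, 2] - tri[3, 2]) * (w[, 1] - tri[3, 1])
        bad <- any(!dup & d1 > 1e-9 & d2 > 1e-9 & d3 > 1e-9)
      }
      if (bad) next
      tris <- rbind(tris, c(a, b, cc))
      idx <- idx[idx != b]
      clipped <- TRUE
      break
    }
    if (!clipped) {
      # fall back: clip the least-reflex corner to guarantee progress
      m <- length(idx)
      best <- 1L; bestcr <- -Inf
      for (k in seq_len(m)) {
        a <- idx[(k - 2L) %% m + 1L]; b <- idx[(k - 1L) %% m + 1L]; cc <- idx[k %% m + 1L]
        v1 <- P[b, ] - P[a, ]; v2 <- P[cc, ] - P[a, ]
        cr <- v1[1] * v2[2] - v1[2] * v2[1]
        if (cr > bestcr) { bestcr <- cr; best <- k }
      }
      a <- idx[(best - 2L) %% m + 1L]; b <- idx[(best - 1L) %% m + 1L]; cc <- idx[best %% m + 1L]
      tris <- rbind(tris, c(a, b, cc))
      idx <- idx[idx != b]
    }
  }
  if (length(idx) == 3L) tris <- rbind(tris, idx)
  tris
}

# Triangulate a planar region bounded by one outer loop and zero or more hole
# loops (2D coordinates). Holes are connected to the outer loop with bridge
# edges, then the resulting simple polygon is ear-clipped. Returns triangles
# as indices into rbind(outer, hole1, hole2, ...).
.triangulate_with_holes <- function(outer, holes = list()) {
  # indices always refer to rbind(outer, holes...) in the caller's row order;
  # orientation is imposed by traversal order, never by permuting the points
  all_pts <- outer
  outer_ids <- seq_len(nrow(outer))
  if (.polygon_area2(outer) < 0) outer_ids <- rev(outer_ids)
  offset <- nrow(outer)
  hole_ids <- list()
  for (h in holes) {
    hi <- offset + seq_len(nrow(h))
    if (.polygon_area2(h) > 0) hi <- rev(hi)  # holes are traversed clockwise
    hole_ids[[length(hole_ids) + 1L]] <- hi
    all_pts <- rbind(all_pts, h)
    offset <- offset + nrow(h)
  }
  poly <- outer_ids
  if (length(holes)) {
    # connect holes in order of decreasing rightmost x (classic bridging)
    rx <- vapply(hole_ids, function(hi) max(all_pts[hi, 1]), numeric(1))
    for (h in order(rx, decreasing = TRUE)) {
      hi <- hole_ids[[h]]
      hk <- hi[which.max(all_pts[hi, 1])]
      # bridge to the visible polygon vertex: nearest to the right
      p <- all_pts[hk, ]
      d <- sqrt(rowSums((all_pts[poly, , drop = FALSE] -
                           matrix(p, length(poly), 2, byrow = TRUE))^2))
      ord <- order(d)
      bridged <- FALSE
      for (cand in ord) {
        ok <- TRUE
        q <- all_pts[poly[cand], ]
        # bridge must not cross existing polygon edges (coarse check)
        m <- length(poly)
        for (e in seq_len(m)) {
          a <- poly[e]; b <- poly[e %% m + 1L]
          if (a == poly[cand] || b == poly[cand]) next
          if (.segments_cross(p, q, all_pts[a, ], all_pts[b, ], touch = TRUE)) { ok <- FALSE; break }
        }
        if (ok) {
          for (e in seq_along(hi)) {
            a <- hi[e]; b <- hi[e %% length(hi) + 1L]
            if (a == hk || b == hk) next
            if (.segments_cross(p, q, all_pts[a, ], all_pts[b, ], touch = TRUE)) { ok <- FALSE; break }
          }
        }
        if (ok) {
          at <- cand
          pos <- which(hi == hk)
          rot <- c(hi[pos:length(hi)], hi[seq_len(pos - 1L)], hk)
          poly <- c(poly[seq_len(at)], rot, poly[at:length(poly)])
          bridged <- TRUE
          break
        }
      }
      if (!bridged) stop("could not bridge a hole into the outer boundary", call. = FALSE)
    }
  }
  tri_local <- .ear_clip(all_pts[poly, , drop = FALSE])
  tri <- matrix(poly[tri_local], ncol = 3)
  # ears spanning both copies of a bridge vertex map to repeated ids; they are
  # zero-area and must be dropped to keep the edge balance intact
  keep <- tri[, 1] != tri[, 2] & tri[, 2] != tri[, 3] & tri[, 1] != tri[, 3]
  tri[keep, , drop = FALSE]
}

.segments_cross <- function(p1, p2, q1, q2, touch = FALSE) {
  # signed distances of each segment's endpoints from the other segment's line
  d <- function(a, b, c) {
    len <- sqrt(sum((b - a)^2))
    ((b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])) / max(len, 1e-12)
  }
  d1 <- d(p1, p2, q1); d2 <- d(p1, p2, q2); d3 <- d(q1, q2, p1); d4 <- d(q1, q2, p2)
  strict <- (d1 * d2 < -1e-12) && (d3 * d4 < -1e-12)
  if (!touch || strict) return(strict)
  # grazing contact: an endpoint of one segment lying on the other
  .point_near_segment(q1, p1, p2) || .point_near_segment(q2, p1, p2) ||
    .point_near_segment(p1, q1, q2) || .point_near_segment(p2, q1, q2)
}

.point_near_segment <- function(q, a, b, tol = 1e-7) {
  ab <- b - a
  t <- sum((q - a) * ab) / max(sum(ab^2), 1e-18)
  t <- min(max(t, 0), 1)
  sqrt(sum((a + t * ab - q)^2)) < tol
}
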