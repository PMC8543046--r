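# Stage-B misalignment correction: the same sequential optimiser as the
# intensity stage, with the pairwise dissimilarity replaced by Euclidean
# distances between contour crossings of the two slices' intersection line.

#' Crossing points of a contour with a line in its plane
#'
#' Exact polyline/line intersections, computed in the contour's plane and
#' returned in 3D, ordered along the line.
#'
#' @param contour a [labelled_contour()].
#' @param plane the owning `slice_plane` at its current pose.
#' @param line a [line3d()] lying in the plane.
#' @return list with `points` (k x 3) and `t` (parameter along the line),
#'   both ordered by `t`; `k = 0` when the line misses the contour.
#' @export
contour_crossings <- function(contour, plane, line) {
  pr <- world_to_plane(plane, rbind(line$point))
  p0 <- pr$xy[1, ]
  d <- c(sum(line$direction * plane$u_axis), sum(line$direction * plane$v_axis))
  P <- contour$points
  n <- nrow(P)
  idx <- if (contour$closed) cbind(seq_len(n), c(2:n, 1)) else cbind(1:(n - 1), 2:n)
  # signed side of each vertex relative to the line
  rel <- sweep(P, 2, p0)
  s <- rel[, 1] * d[2] - rel[, 2] * d[1]
  sa <- s[idx[, 1]]; sb <- s[idx[, 2]]
  crossing <- (sa <= 0 & sb > 0) | (sa > 0 & sb <= 0)
  if (!any(crossing)) return(list(points = matrix(0, 0, 3), t = numeric(0)))
  ia <- idx[crossing, 1]; ib <- idx[crossing, 2]
  f <- sa[crossing] / (sa[crossing] - sb[crossing])
  Q <- P[ia, , drop = FALSE] + f * (P[ib, , drop = FALSE] - P[ia, , drop = FALSE])
  t <- (Q[, 1] - p0[1]) * d[1] + (Q[, 2] - p0[2]) * d[2]
  ord <- order(t)
  Q3 <- plane_to_world(plane, Q[ord, , drop = FALSE])
  list(points = Q3, t = t[ord])
}

# anatomically compatible partner labels for crossing matching; the septum is
# the shared wall between LV epicardium and RV endocardium, so its crossings
# compare against both. Synthesized RV epicardial contours are excluded.
.partner_labels <- function(label) {
  switch(label,
         LV_ENDO = "LV_ENDO",
         LV_EPI = c("LV_EPI", "SEPTUM"),
         SEPTUM = c("SEPTUM", "LV_EPI", "RV_ENDO"),
         RV_ENDO = c("RV_ENDO", "SEPTUM"),
         RV_EPI = character(0),
         character(0))
}

# greedy nearest-first matching of two sorted position vectors along a line;
# ties break toward preserving order
.match_crossings <- function(ti, tj) {
  if (length(ti) == 0 || length(tj) == 0) return(NULL)
  grid <- expand.grid(i = seq_along(ti), j = seq_along(tj))
  grid$d <- abs(ti[grid$i] - tj[grid$j])
  grid <- grid[order(grid$d, grid$i, grid$j), ]
  used_i <- logical(length(ti)); used_j <- logical(length(tj))
  out <- list()
  for (k in seq_len(nrow(grid))) {
    i <- grid$i[k]; j <- grid$j[k]
    if (used_i[i] || used_j[j]) next
    used_i[i] <- TRUE; used_j[j] <- TRUE
    out[[length(out) + 1L]] <- c(i, j, grid$d[k])
  }
  do.call(rbind, out)
}

#' Contour-crossing dissimilarity of two slices
#'
#' For every anatomically compatible label pair present on both slices, the
#' crossings of each slice's contours with the shared intersection line are
#' matched greedily nearest-first along the line; `E` is the mean Euclidean
#' distance over all matched pairs pooled across labels.
#'
#' @param plane_i,plane_j `slice_plane`s at their current poses.
#' @param cons_i,cons_j lists of [labelled_contour()]s owned by each slice.
#' @param line optional precomputed intersection line.
#' @param details also return the per-match table.
#' @return the scalar dissimilarity (`NA` = pair skipped), or a list with
#'   `e` and `matches` when `details = TRUE`.
#' @export
contour_pair_dissimilarity <- function(plane_i, cons_i, plane_j, cons_j,
                                       line = NULL, details = FALSE) {
  skip <- function() if (details) list(e = NA_real_, matches = NULL) else NA_real_
  if (length(cons_i) == 0 || length(cons_j) == 0) return(skip())
  if (is.null(line)) line <- plane_intersection_line(plane_i, plane_j)
  if (is.null(line)) return(skip())
  labs_i <- vapply(cons_i, `[[`, character(1), "label")
  labs_j <- vapply(cons_j, `[[`, character(1), "label")
  cross_for <- function(cons, plane, keep) {
    ts <- numeric(0)
    for (cc in cons[keep]) {
      cr <- contour_crossings(cc, plane, line)
      ts <- c(ts, cr$t)
    }
    sort(ts)
  }
  dists <- numeric(0)
  matches <- list()
  for (L in intersect(unique(labs_i), .label_levels)) {
    partners <- .partner_labels(L)
    if (length(partners) == 0) next
    ti <- cross_for(cons_i, plane_i, labs_i == L)
    tj <- cross_for(cons_j, plane_j, labs_j %in% partners)
    m <- .match_crossings(ti, tj)
    if (is.null(m)) next
    dists <- c(dists, m[, 3])
    matches[[length(matches) + 1L]] <-
      data.frame(label = L, t_i = ti[m[, 1]], t_j = tj[m[, 2]], distance = m[, 3])
  }
  if (length(dists) == 0) return(skip())
  e <- mean(dists)
  if (details) list(e = e, matches = do.call(rbind, matches)) else e
}

#' Stage-B contours-based misalignment correction
#'
#' Runs the sequential per-slice optimiser with the contour-crossing
#' dissimilarity, starting from the stage-A poses.
#'
#' @param planes list of `slice_plane`s (original poses).
#' @param contours list (one element per slice) of lists of
#'   [labelled_contour()]s.
#' @param thetas0 stage-A output poses as initialisation.
#' @param step_min final pattern-search step (mm / deg).
#' @param ... passed to [optimize_slicewise()].
#' @return list with `thetas`, `gm_trace`, `skipped`, and `residuals` — a
#'   data.frame of per-label mean/SD matched crossing distances before and
#'   after correction.
#' @export
correct_contours <- function(planes, contours, thetas0 = NULL, step_min = 0.05, ...) {
  layout <- classify_slices(planes)
  packed <- lapply(contours, .pack_contours)
  dissim <- function(pa, pb, ca, cb) {
    if (is.null(ca) || is.null(cb)) return(NA_real_)
    cpp_contour_pair_E(pa$origin, pa$u_axis, pa$v_axis,
                       ca$pts, ca$start, ca$len, ca$lab, ca$closed,
                       pb$origin, pb$u_axis, pb$v_axis,
                       cb$pts, cb$start, cb$len, cb$lab, cb$closed)
  }
  res_before <- .crossing_residual_table(planes, contours, thetas0)
  res <- optimize_slicewise(planes, dissim, data = packed,
                            lax_idx = layout$lax_idx, thetas0 = thetas0,
                            step_min = step_min, ...)
  if (!is.null(thetas0)) {
    # the stage-A initialisation usually helps but can occasionally steer the
    # sequential optimiser into a worse self-consistent configuration; a
    # second start from the raw acquisition poses guards against that, and
    # the lower final objective wins
    res_cold <- optimize_slicewise(planes, dissim, data = packed,
                                   lax_idx = layout$lax_idx, thetas0 = NULL,
                                   step_min = step_min, ...)
    if (tail(res_cold$gm_trace, 1) < tail(res$gm_trace, 1)) res <- res_cold
  }
  res_after <- .crossing_residual_table(planes, contours, res$thetas)
  res_before$stage <- "before"
  res_after$stage <- "after"
  res$residuals <- rbind(res_before, res_after)
  res$layout <- layout
  res
}

# per-label mean/SD of matched crossing distances over all intersecting pairs
.crossing_residual_table <- function(planes, contours, thetas = NULL) {
  n <- length(planes)
  if (is.null(thetas)) thetas <- replicate(n, rigid_params(), simplify = FALSE)
  pt <- mapply(apply_rigid, planes, thetas, SIMPLIFY = FALSE)
  all_m <- list()
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    r <- contour_pair_dissimilarity(pt[[i]], contours[[i]], pt[[j]], contours[[j]],
                                    details = TRUE)
    if (!is.null(r$matches)) all_m[[length(all_m) + 1L]] <- r$matches
  }
  if (length(all_m) == 0)
    return(data.frame(label = character(0), mean = numeric(0), sd = numeric(0),
                      n = integer(0)))
  m <- do.call(rbind, all_m)
  agg <- do.call(rbind, lapply(split(m$distance, m$label), function(d) {
    data.frame(mean = mean(d), sd = sd(d), n = length(d))
  }))
  agg$label <- rownames(agg)
  pooled <- data.frame(mean = mean(m$distance), sd = sd(m$distance),
                       n = nrow(m), label = "POOLED")
  rownames(agg) <- NULL
  rbind(agg[, c("label", "mean", "sd", "n")], pooled[, c("label", "mean", "sd", "n")])
}

# pack per-slice contours into flat arrays for the C++ dissimilarity kernel;
# labels coded 1 LV_ENDO, 2 LV_EPI, 3 RV_ENDO, 4 SEPTUM, 5 RV_EPI
.pack_contours <- function(cons) {
  cons <- Filter(function(cc) cc$label %in% .label_levels, cons)
  if (length(cons) == 0) return(NULL)
  pts <- do.call(rbind, lapply(cons, `[[`, "points"))
  len <- vapply(cons, function(cc) nrow(cc$points), integer(1))
  start <- c(0L, cumsum(len)[-length(len)])
  lab <- match(vapply(cons, `[[`, character(1), "label"), .label_levels)
  closed <- vapply(cons, `[[`, logical(1), "closed")
  list(pts = pts, start = as.integer(start), len = as.integer(len),
       lab = as.integer(lab), closed = closed)
}
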