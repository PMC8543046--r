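# Slice-pose algebra: planes with DICOM-style geometry, rigid per-slice
# transforms, plane/plane intersection, and contour lifting between the
# in-plane (mm) frame and patient space.

.unit <- function(v) {
  n <- sqrt(sum(v^2))
  if (n == 0) stop("zero-length vector cannot be normalised", call. = FALSE)
  v / n
}

.cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Construct a slice plane
#'
#' A `slice_plane` carries the full 3D pose of one cine slice: the patient-space
#' position of the centre of pixel (row 0, col 0), the in-plane unit axes along
#' increasing column and row index, the pixel spacing in mm, the grid shape,
#' and optionally the pixel data itself. The plane normal is
#' `u_axis x v_axis`. The mapping from (row i, col j) to patient space is
#' `origin + j * spacing[1] * u_axis + i * spacing[2] * v_axis` (0-based
#' indices addressing pixel centres).
#'
#' @param origin 3-vector, mm.
#' @param u_axis,v_axis orthonormal in-plane unit 3-vectors.
#' @param spacing length-2 vector `(mm per column step, mm per row step)`.
#' @param shape integer `(n_rows, n_cols)`.
#' @param pixels optional `n_rows x n_cols` matrix of intensities.
#' @param view one of `"SAX"`, `"LAX"`, `"UNKNOWN"`.
#' @param id optional identifier used in reports.
#' @return An object of class `slice_plane`.
#' @export
slice_plane <- function(origin, u_axis, v_axis, spacing, shape,
                        pixels = NULL, view = "UNKNOWN", id = NULL) {
  origin <- as.numeric(origin)
  u_axis <- as.numeric(u_axis)
  v_axis <- as.numeric(v_axis)
  if (length(origin) != 3L || length(u_axis) != 3L || length(v_axis) != 3L)
    stop("origin, u_axis and v_axis must be 3-vectors", call. = FALSE)
  if (abs(sqrt(sum(u_axis^2)) - 1) > 1e-9 || abs(sqrt(sum(v_axis^2)) - 1) > 1e-9)
    stop("malformed geometry: u_axis and v_axis must be unit vectors", call. = FALSE)
  if (abs(sum(u_axis * v_axis)) > 1e-9)
    stop("malformed geometry: u_axis and v_axis must be orthogonal", call. = FALSE)
  spacing <- as.numeric(spacing)
  if (length(spacing) != 2L || any(spacing <= 0))
    stop("spacing must be two positive values (mm/col, mm/row)", call. = FALSE)
  shape <- as.integer(shape)
  if (length(shape) != 2L || any(shape < 1L))
    stop("shape must be (n_rows, n_cols), both >= 1", call. = FALSE)
  if (!is.null(pixels)) {
    pixels <- as.matrix(pixels)
    if (!all(dim(pixels) == shape))
      stop("pixels dimensions must equal shape", call. = FALSE)
  }
  view <- match.arg(view, c("UNKNOWN", "SAX", "LAX"))
  structure(list(origin = origin, u_axis = u_axis, v_axis = v_axis,
                 spacing = spacing, shape = shape, pixels = pixels,
                 view = view, id = id),
            class = "slice_plane")
}

#' @export
print.slice_plane <- function(x, ...) {
  cat(sprintf("<slice_plane%s %dx%d @ %.4gx%.4g mm, view %s%s>\n",
              if (is.null(x$id)) "" else paste0(" '", x$id, "'"),
              x$shape[1], x$shape[2], x$spacing[2], x$spacing[1], x$view,
              if (is.null(x$pixels)) ", no pixels" else ""))
  invisible(x)
}

#' Plane normal (unit vector)
#' @param plane a `slice_plane`.
#' @return unit 3-vector `u_axis x v_axis`.
#' @export
plane_normal <- function(plane) .unit(.cross3(plane$u_axis, plane$v_axis))

#' 3D position of the pixel-grid centre
#' @param plane a `slice_plane`.
#' @return 3-vector, mm.
#' @export
plane_grid_center <- function(plane) {
  plane$origin +
    (plane$shape[2] - 1) / 2 * plane$spacing[1] * plane$u_axis +
    (plane$shape[1] - 1) / 2 * plane$spacing[2] * plane$v_axis
}

#' Map in-plane mm coordinates to patient space
#'
#' In-plane coordinates `(x, y)` are measured in mm along `u_axis` and
#' `v_axis` from the plane origin; pixel (i, j) sits at
#' `x = j * spacing[1]`, `y = i * spacing[2]`.
#'
#' @param plane a `slice_plane`.
#' @param xy n x 2 matrix of in-plane mm coordinates.
#' @return n x 3 matrix of patient-space points.
#' @export
plane_to_world <- function(plane, xy) {
  xy <- rbind(xy)  # tolerate a single point as a vector
  if (ncol(xy) != 2L) stop("xy must be n x 2", call. = FALSE)
  outer(rep(1, nrow(xy)), plane$origin) +
    xy[, 1, drop = FALSE] %*% rbind(plane$u_axis) +
    xy[, 2, drop = FALSE] %*% rbind(plane$v_axis)
}

#' Project patient-space points onto a plane's in-plane frame
#'
#' @param plane a `slice_plane`.
#' @param pts n x 3 matrix of patient-space points.
#' @return list with `xy` (n x 2 in-plane mm) and `w` (signed out-of-plane
#'   distance along the normal, mm).
#' @export
world_to_plane <- function(plane, pts) {
  pts <- rbind(pts)
  d <- sweep(pts, 2, plane$origin)
  list(xy = cbind(d %*% plane$u_axis, d %*% plane$v_axis),
       w = as.numeric(d %*% plane_normal(plane)))
}

# ---------------------------------------------------------------------------

#' Rigid per-slice transform parameters
#'
#' Three translations (mm) along the slice's current `u_axis`, `v_axis` and
#' normal, plus three intrinsic Euler angles (degrees): `gamma` about the
#' normal, then `beta` about `u_axis`, then `alpha` about `v_axis`, all
#' pivoted at the slice's pixel-grid centre. With `inplane_only = TRUE` the
#' out-of-plane components `tz`, `alpha`, `beta` must be exactly zero.
#'
#' @param tx,ty,tz translations, mm.
#' @param alpha,beta,gamma rotations, degrees.
#' @param inplane_only restrict to the in-plane subset `(tx, ty, gamma)`.
#' @return An object of class `rigid_params`.
#' @export
rigid_params <- function(tx = 0, ty = 0, tz = 0,
                         alpha = 0, beta = 0, gamma = 0,
                         inplane_only = FALSE) {
  if (inplane_only && (tz != 0 || alpha != 0 || beta != 0))
    stop("inplane_only transforms require tz = alpha = beta = 0", call. = FALSE)
  structure(list(tx = tx, ty = ty, tz = tz,
                 alpha = alpha, beta = beta, gamma = gamma,
                 inplane_only = inplane_only),
            class = "rigid_params")
}

#' @export
print.rigid_params <- function(x, ...) {
  cat(sprintf("<rigid t=(%.3g, %.3g, %.3g) mm, r=(%.3g, %.3g, %.3g) deg%s>\n",
              x$tx, x$ty, x$tz, x$alpha, x$beta, x$gamma,
              if (x$inplane_only) ", in-plane" else ""))
  invisible(x)
}

#' In-plane rigid transform
#' @param tx,ty translations, mm; `gamma` rotation about the slice normal, degrees.
#' @param gamma rotation about slice normal, degrees.
#' @return `rigid_params` with `inplane_only = TRUE`.
#' @export
rigid_inplane <- function(tx = 0, ty = 0, gamma = 0) {
  rigid_params(tx = tx, ty = ty, gamma = gamma, inplane_only = TRUE)
}

.axis_rotation <- function(axis, angle_deg) {
  a <- angle_deg * pi / 180
  u <- .unit(axis)
  c <- cos(a); s <- sin(a)
  ux <- u[1]; uy <- u[2]; uz <- u[3]
  matrix(c(c + ux^2 * (1 - c), ux * uy * (1 - c) - uz * s, ux * uz * (1 - c) + uy * s,
           uy * ux * (1 - c) + uz * s, c + uy^2 * (1 - c), uy * uz * (1 - c) - ux * s,
           uz * ux * (1 - c) - uy * s, uz * uy * (1 - c) + ux * s, c + uz^2 * (1 - c)),
         nrow = 3, byrow = TRUE)
}

#' World-space affine map of a rigid transform
#'
#' Returns the map `x -> R x + b` realising `theta` on `plane` (rotation about
#' the grid centre in the order gamma, beta, alpha; then translation along the
#' plane's axes).
#'
#' @param theta `rigid_params`.
#' @param plane the `slice_plane` the parameters refer to.
#' @return list with rotation matrix `R` and offset `b`.
#' @export
rigid_to_affine <- function(theta, plane) {
  u <- plane$u_axis; v <- plane$v_axis; n <- plane_normal(plane)
  R <- .axis_rotation(v, theta$alpha) %*%
       .axis_rotation(u, theta$beta) %*%
       .axis_rotation(n, theta$gamma)
  ctr <- plane_grid_center(plane)
  b <- ctr - R %*% ctr + theta$tx * u + theta$ty * v + theta$tz * n
  list(R = R, b = as.numeric(b))
}

#' Recover rigid parameters from a world-space affine map
#'
#' Inverse of [rigid_to_affine()]: decomposes a rigid map into the six
#' parameters relative to `plane` (Euler pattern: rotation about v, then u,
#' then normal).
#'
#' @param affine list with `R` and `b`.
#' @param plane reference `slice_plane`.
#' @return `rigid_params`.
#' @export
affine_to_rigid <- function(affine, plane) {
  u <- plane$u_axis; v <- plane$v_axis; n <- plane_normal(plane)
  U <- cbind(u, v, n)
  M <- t(U) %*% affine$R %*% U
  beta <- asin(max(-1, min(1, -M[2, 3])))
  alpha <- atan2(M[1, 3], M[3, 3])
  gamma <- atan2(M[2, 1], M[2, 2])
  ctr <- plane_grid_center(plane)
  tr <- as.numeric(t(U) %*% (affine$b - ctr + affine$R %*% ctr))
  rigid_params(tx = tr[1], ty = tr[2], tz = tr[3],
               alpha = alpha * 180 / pi, beta = beta * 180 / pi,
               gamma = gamma * 180 / pi)
}

#' Apply a rigid transform to a slice plane
#'
#' Pose-only: pixel data are untouched; the origin and axes move. Rotation is
#' pivoted at the pixel-grid centre, translation acts along the slice's
#' current axes.
#'
#' @param plane a `slice_plane`.
#' @param theta `rigid_params`.
#' @return the transformed `slice_plane`.
#' @export
apply_rigid <- function(plane, theta) {
  if (theta$tx == 0 && theta$ty == 0 && theta$tz == 0 &&
      theta$alpha == 0 && theta$beta == 0 && theta$gamma == 0)
    return(plane)  # identity leaves the pose bit-identical
  af <- rigid_to_affine(theta, plane)
  out <- plane
  out$origin <- as.numeric(af$R %*% plane$origin + af$b)
  out$u_axis <- .unit(as.numeric(af$R %*% plane$u_axis))
  out$v_axis <- .unit(as.numeric(af$R %*% plane$v_axis))
  # re-orthogonalise against numerical drift
  out$v_axis <- .unit(out$v_axis - sum(out$v_axis * out$u_axis) * out$u_axis)
  out
}

#' Compose two rigid transforms
#'
#' Parameters such that applying the result to `plane` equals applying `t1`
#' then `t2` (with `t2` interpreted relative to the plane already moved by
#' `t1`, as in sequential optimisation sweeps).
#'
#' @param t1,t2 `rigid_params`.
#' @param plane the original `slice_plane`.
#' @return composed `rigid_params` relative to `plane`.
#' @export
compose_rigid <- function(t1, t2, plane) {
  a1 <- rigid_to_affine(t1, plane)
  p1 <- apply_rigid(plane, t1)
  a2 <- rigid_to_affine(t2, p1)
  R <- a2$R %*% a1$R
  b <- as.numeric(a2$R %*% a1$b + a2$b)
  affine_to_rigid(list(R = R, b = b), plane)
}

#' Inverse rigid transform
#'
#' Parameters that undo `theta`: applying `theta` to `plane` and then the
#' result restores the original pose.
#'
#' @param theta `rigid_params`.
#' @param plane the original `slice_plane`.
#' @return `rigid_params` relative to the transformed plane.
#' @export
invert_rigid <- function(theta, plane) {
  af <- rigid_to_affine(theta, plane)
  Rinv <- t(af$R)
  binv <- as.numeric(-Rinv %*% af$b)
  affine_to_rigid(list(R = Rinv, b = binv), apply_rigid(plane, theta))
}

# ---------------------------------------------------------------------------

#' 3D line
#' @param point a point on the line, mm.
#' @param direction direction (normalised internally).
#' @return object of class `line3d`.
#' @export
line3d <- function(point, direction) {
  structure(list(point = as.numeric(point), direction = .unit(as.numeric(direction))),
            class = "line3d")
}

#' Intersection line of two slice planes
#'
#' @param a,b `slice_plane`s.
#' @return a `line3d`, or `NULL` when the planes are parallel
#'   (`|n_a . n_b| > 1 - 1e-6`).
#' @export
plane_intersection_line <- function(a, b) {
  na <- plane_normal(a); nb <- plane_normal(b)
  if (abs(sum(na * nb)) > 1 - 1e-6) return(NULL)
  d <- .unit(.cross3(na, nb))
  A <- rbind(na, nb, d)
  rhs <- c(sum(na * a$origin), sum(nb * b$origin), sum(d * (a$origin + b$origin) / 2))
  line3d(point = solve(A, rhs), direction = d)
}

# ---------------------------------------------------------------------------

#' Labelled anatomical contour
#'
#' An ordered polyline in a slice's in-plane mm frame with one of the five
#' anatomical labels (LV endocardium, LV epicardium, RV endocardium, septum,
#' synthesized RV epicardium).
#'
#' @param label one of `LV_ENDO`, `LV_EPI`, `RV_ENDO`, `SEPTUM`, `RV_EPI`.
#' @param points n x 2 matrix of in-plane mm coordinates, ordered.
#' @param closed whether the polyline closes back to its first point.
#' @param slice_id identifier of the owning slice plane.
#' @return object of class `labelled_contour`.
#' @export
labelled_contour <- function(label, points, closed = FALSE, slice_id = NULL) {
  label <- match.arg(label, c(.label_levels, "EPI"))
  points <- as.matrix(points)
  if (ncol(points) != 2L || nrow(points) < 3L)
    stop("a contour needs at least 3 in-plane points", call. = FALSE)
  seg <- sqrt(rowSums((points[-1, , drop = FALSE] -
                         points[-nrow(points), , drop = FALSE])^2))
  if (any(seg <= 1e-6))
    stop("consecutive contour points must be > 1e-6 mm apart", call. = FALSE)
  structure(list(label = label, points = unname(points), closed = isTRUE(closed),
                 slice_id = slice_id),
            class = "labelled_contour")
}

#' @export
print.labelled_contour <- function(x, ...) {
  cat(sprintf("<contour %s, %d pts, %s%s>\n", x$label, nrow(x$points),
              if (x$closed) "closed" else "open",
              if (is.null(x$slice_id)) "" else paste0(", slice ", x$slice_id)))
  invisible(x)
}

#' Lift a contour to patient space
#'
#' @param contour a `labelled_contour`.
#' @param plane the owning `slice_plane` (at its current pose).
#' @return n x 3 matrix of patient-space points.
#' @export
contour_to_3d <- function(contour, plane) {
  plane_to_world(plane, contour$points)
}
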