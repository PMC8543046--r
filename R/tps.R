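# 3D thin-plate splines: interpolating deformation with the |r| kernel,
# exact at the control points, reproducing affine maps with zero bending
# energy. Used to pull reconstructed surfaces onto the sparse contours.

#' Fit a 3D thin-plate-spline warp
#'
#' Solves the standard TPS interpolation system with kernel `U(r) = r`:
#' the warp maps every control point exactly onto its target and reproduces
#' any affine map with zero bending energy. Duplicate control points (within
#' 1e-9 mm) are merged, averaging their targets. Coplanar controls cannot
#' support the kernel system; the fit falls back to the affine part alone with
#' a warning.
#'
#' @param control k x 3 matrix of source points.
#' @param targets k x 3 matrix of target points.
#' @param reg small ridge added to the kernel diagonal (0 = exact
#'   interpolation).
#' @return object of class `tps_warp` with elements `control`, `weights`,
#'   `affine` (4 x 3: row 1 offset, rows 2-4 linear part), `bending_energy`.
#' @export
tps_warp <- function(control, targets, reg = 0) {
  control <- as.matrix(control); targets <- as.matrix(targets)
  stopifnot(ncol(control) == 3, ncol(targets) == 3,
            nrow(control) == nrow(targets))
  # merge duplicates
  key <- apply(round(control / 1e-9) * 1e-9, 1, paste, collapse = "_")
  if (anyDuplicated(key)) {
    groups <- split(seq_len(nrow(control)), key)
    control <- do.call(rbind, lapply(groups, function(g) control[g[1], ]))
    targets <- do.call(rbind, lapply(groups, function(g)
      colMeans(targets[g, , drop = FALSE])))
  }
  k <- nrow(control)
  if (k < 4) stop("at least 4 distinct control points required", call. = FALSE)
  # coplanarity check
  ctr <- colMeans(control)
  sv <- svd(sweep(control, 2, ctr))$d
  if (sv[3] < 1e-9 * max(sv[1], 1)) {
    warning("coplanar control points: falling back to an affine-only fit")
    X <- cbind(1, control)
    # rank-deficient least squares (the controls span only a plane)
    sv <- svd(X)
    pos <- sv$d > 1e-9 * sv$d[1]
    A <- sv$v[, pos, drop = FALSE] %*% (t(sv$u[, pos, drop = FALSE]) %*% targets /
                                          sv$d[pos])
    return(structure(list(control = control, weights = matrix(0, k, 3),
                          affine = A, bending_energy = 0),
                     class = "tps_warp"))
  }
  K <- as.matrix(dist(control))
  if (reg > 0) K <- K + diag(reg, k)
  P <- cbind(1, control)
  L <- rbind(cbind(K, P), cbind(t(P), matrix(0, 4, 4)))
  rhs <- rbind(targets, matrix(0, 4, 3))
  sol <- solve(L, rhs)
  W <- sol[seq_len(k), , drop = FALSE]
  A <- sol[k + 1:4, , drop = FALSE]
  be <- sum(diag(t(W) %*% K %*% W))
  structure(list(control = control, weights = W, affine = A,
                 bending_energy = be),
            class = "tps_warp")
}

#' Apply a TPS warp to points
#'
#' @param warp a [tps_warp()].
#' @param points n x 3 matrix.
#' @return warped n x 3 matrix.
#' @export
tps_apply <- function(warp, points) {
  points <- rbind(points)
  # pairwise distances query x control
  d2 <- outer(rowSums(points^2), rep(1, nrow(warp$control))) +
    outer(rep(1, nrow(points)), rowSums(warp$control^2)) -
    2 * points %*% t(warp$control)
  U <- sqrt(pmax(d2, 0))
  cbind(1, points) %*% warp$affine + U %*% warp$weights
}

#' @export
print.tps_warp <- function(x, ...) {
  cat(sprintf("<tps_warp: %d controls, bending energy %.4g>\n",
              nrow(x$control), x$bending_energy))
  invisible(x)
}
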