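# Shared fixtures (computed once per test session) and independent oracles.

.fx <- new.env(parent = emptyenv())

fx_spec <- function() {
  if (is.null(.fx$spec)) .fx$spec <- phantom_spec()
  .fx$spec
}

fx_planes <- function() {
  if (is.null(.fx$planes)) .fx$planes <- default_study_planes(fx_spec())
  .fx$planes
}

fx_contours <- function() {
  if (is.null(.fx$contours))
    .fx$contours <- lapply(fx_planes(), function(p) analytic_contours(fx_spec(), p))
  .fx$contours
}

fx_truth <- function() {
  if (is.null(.fx$truth)) .fx$truth <- make_phantom_surfaces(fx_spec())
  .fx$truth
}

fx_small_ssm <- function() {
  if (is.null(.fx$ssm))
    .fx$ssm <- make_synthetic_ssm(fx_spec(), n_samples = 60, n_modes = 40, seed = 101)
  .fx$ssm
}

# small canonical planes
plane_z0 <- function(n = 32, spacing = 1, id = "z0") {
  slice_plane(origin = c(-(n - 1) / 2 * spacing, -(n - 1) / 2 * spacing, 0),
              u_axis = c(1, 0, 0), v_axis = c(0, 1, 0),
              spacing = c(spacing, spacing), shape = c(n, n), id = id)
}

plane_from_normal <- function(normal, origin = c(0, 0, 0), n = 32, spacing = 1,
                              id = NULL) {
  normal <- normal / sqrt(sum(normal^2))
  ref <- if (abs(normal[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  u <- ref - sum(ref * normal) * normal
  u <- u / sqrt(sum(u^2))
  v <- c(normal[2] * u[3] - normal[3] * u[2],
         normal[3] * u[1] - normal[1] * u[3],
         normal[1] * u[2] - normal[2] * u[1])
  slice_plane(origin = origin - (n - 1) / 2 * spacing * (u + v),
              u_axis = u, v_axis = v, spacing = c(spacing, spacing),
              shape = c(n, n), id = id)
}

# circle contour in a plane's in-plane frame, centred on the pixel grid
circle_contour <- function(plane, radius, n = 128, label = "LV_ENDO") {
  ctr <- c((plane$shape[2] - 1) / 2 * plane$spacing[1],
           (plane$shape[1] - 1) / 2 * plane$spacing[2])
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  labelled_contour(label, cbind(ctr[1] + radius * cos(th), ctr[2] + radius * sin(th)),
                   closed = TRUE, slice_id = plane$id)
}

# ---- independent oracles ---------------------------------------------------

# point-to-triangle distance via plane projection + 2D barycentric test +
# segment distances (a different formulation from the package kernel)
oracle_point_tri <- function(p, a, b, c) {
  cross3 <- function(x, y) c(x[2] * y[3] - x[3] * y[2],
                             x[3] * y[1] - x[1] * y[3],
                             x[1] * y[2] - x[2] * y[1])
  n <- cross3(b - a, c - a)
  nl <- sqrt(sum(n^2))
  if (nl < 1e-15) return(min(sqrt(sum((p - a)^2)), sqrt(sum((p - b)^2))))
  n <- n / nl
  q <- p - sum((p - a) * n) * n
  # barycentric coordinates of q
  v0 <- b - a; v1 <- c - a; v2 <- q - a
  d00 <- sum(v0 * v0); d01 <- sum(v0 * v1); d11 <- sum(v1 * v1)
  d20 <- sum(v2 * v0); d21 <- sum(v2 * v1)
  den <- d00 * d11 - d01 * d01
  v <- (d11 * d20 - d01 * d21) / den
  w <- (d00 * d21 - d01 * d20) / den
  if (v >= 0 && w >= 0 && v + w <= 1) return(abs(sum((p - a) * n)))
  seg <- function(x, y) {
    t <- sum((p - x) * (y - x)) / sum((y - x)^2)
    t <- min(max(t, 0), 1)
    sqrt(sum((x + t * (y - x) - p)^2))
  }
  min(seg(a, b), seg(b, c), seg(c, a))
}

oracle_point_mesh <- function(pts, mesh) {
  apply(rbind(pts), 1, function(p) {
    min(apply(mesh$triangles, 1, function(f)
      oracle_point_tri(p, mesh$vertices[f[1], ], mesh$vertices[f[2], ],
                       mesh$vertices[f[3], ])))
  })
}

# Monte Carlo volume of an implicit region within a bounding box
oracle_mc_volume <- function(f, lo, hi, n = 4e5, seed = 99) {
  set.seed(seed)
  pts <- cbind(runif(n, lo[1], hi[1]), runif(n, lo[2], hi[2]), runif(n, lo[3], hi[3]))
  mean(f(pts)) * prod(hi - lo)
}

# spatial-domain circular convolution with the quadrature kernel (the kernel
# itself comes from the frequency response, but the convolution is done as an
# explicit O(N^2) spatial sum - an independent path from the package's
# multiply-in-frequency implementation)
oracle_phase_at <- function(pixels, params, i, j) {
  nr <- nrow(pixels); nc <- ncol(pixels)
  fy <- (seq_len(nr) - 1); fy[fy > nr / 2] <- fy[fy > nr / 2] - nr; fy <- fy / nr
  fx <- (seq_len(nc) - 1); fx[fx > nc / 2] <- fx[fx > nc / 2] - nc; fx <- fx / nc
  R <- sqrt(outer(fy^2, fx^2, `+`)); R[1, 1] <- 1
  A <- atan2(outer(fy, rep(1, nc)), outer(rep(1, nr), fx))
  log_bw2 <- 2 * log(params$bandwidth)^2
  sigma_theta <- 0.66 * pi / params$n_orient
  best <- 0 + 0i; best_amp <- -1
  for (o in seq_len(params$n_orient)) {
    theta <- (o - 1) * pi / params$n_orient
    ds <- atan2(sin(A - theta), cos(A - theta))
    ang <- exp(-ds^2 / (2 * sigma_theta^2))
    G <- matrix(0, nr, nc)
    for (s in seq_len(params$n_scales)) {
      f0 <- 1 / (params$min_wavelength * params$mult^(s - 1))
      rad <- exp(-(log(R / f0))^2 / log_bw2)
      rad[1, 1] <- 0
      G <- G + rad * ang
    }
    h <- fft(G, inverse = TRUE) / (nr * nc)   # spatial kernel, circular
    resp <- 0 + 0i
    for (x in seq_len(nr)) for (y in seq_len(nc)) {
      resp <- resp + pixels[x, y] * h[((i - x) %% nr) + 1, ((j - y) %% nc) + 1]
    }
    if (Mod(resp) > best_amp) { best_amp <- Mod(resp); best <- resp }
  }
  best
}

# best common rigid motion between two point sets (gauge fixing for pose
# evaluation), returns the residual per point after removing it
gauge_fixed_residual <- function(X, Y) {
  cx <- colMeans(X); cy <- colMeans(Y)
  H <- t(sweep(X, 2, cx)) %*% sweep(Y, 2, cy)
  sv <- svd(H)
  R <- sv$v %*% diag(c(1, 1, det(sv$v %*% t(sv$u)))) %*% t(sv$u)
  Yhat <- sweep(sweep(X, 2, cx) %*% t(R), 2, cy, `+`)
  sqrt(rowSums((Y - Yhat)^2))
}
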