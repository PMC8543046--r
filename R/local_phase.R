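# Local phase from banks of quadrature log-Gabor filters, computed in the
# Fourier domain. Local phase is independent of image contrast, which is what
# makes intensity profiles from different slices comparable.

#' Log-Gabor filter bank parameters
#'
#' @param n_scales number of wavelet scales.
#' @param min_wavelength shortest wavelength, pixels.
#' @param mult wavelength multiplier between scales.
#' @param n_orient number of filter orientations over half a turn.
#' @param bandwidth sigma/f ratio of the radial log-Gabor (0.55 gives about
#'   two octaves).
#' @return object of class `filter_bank_params`.
#' @export
filter_bank_params <- function(n_scales = 4, min_wavelength = 4, mult = 2,
                               n_orient = 6, bandwidth = 0.55) {
  stopifnot(n_scales >= 1, min_wavelength > 2, mult > 1,
            n_orient >= 1, bandwidth > 0, bandwidth < 1)
  structure(list(n_scales = n_scales, min_wavelength = min_wavelength,
                 mult = mult, n_orient = n_orient, bandwidth = bandwidth),
            class = "filter_bank_params")
}

# frequency coordinate along one axis in unshifted FFT order, cycles/pixel
.fft_freq <- function(n) {
  f <- seq.int(0, n - 1)
  f[f > n / 2] <- f[f > n / 2] - n
  f / n
}

#' Local phase and amplitude of a 2D image
#'
#' Convolves the image with quadrature pairs of log-Gabor filters (one complex
#' filter per scale and orientation, single-lobed in the frequency domain),
#' sums responses over scales, takes the orientation of maximal amplitude per
#' pixel, and returns its argument as the local phase in (-pi, pi]. Pixels
#' whose amplitude falls below a noise floor are flagged invalid (NA phase).
#'
#' @param pixels numeric matrix.
#' @param params a [filter_bank_params()].
#' @param noise_floor_frac invalidity threshold as a fraction of the 99th
#'   amplitude percentile.
#' @return list with `phase` (matrix, NA where invalid), `amplitude`, `valid`.
#' @export
local_phase_image <- function(pixels, params = filter_bank_params(),
                              noise_floor_frac = 0.05) {
  pixels <- as.matrix(pixels)
  nr <- nrow(pixels); nc <- ncol(pixels)
  max_wl <- params$min_wavelength * params$mult^(params$n_scales - 1)
  if (min(nr, nc) < max_wl)
    stop(sprintf("image (%d x %d) smaller than the largest wavelength (%g px)",
                 nr, nc, max_wl), call. = FALSE)
  fy <- .fft_freq(nr); fx <- .fft_freq(nc)
  R <- sqrt(outer(fy^2, fx^2, `+`))
  A <- atan2(outer(fy, rep(1, nc)), outer(rep(1, nr), fx))
  R[1, 1] <- 1  # avoid log(0); the DC gain is zeroed below
  FI <- fft(pixels)
  log_bw2 <- 2 * log(params$bandwidth)^2
  sigma_theta <- 0.66 * pi / params$n_orient
  best_amp <- matrix(0, nr, nc)
  best_resp <- matrix(complex(real = 0, imaginary = 0), nr, nc)
  for (o in seq_len(params$n_orient)) {
    theta <- (o - 1) * pi / params$n_orient
    ds <- atan2(sin(A - theta), cos(A - theta))
    ang <- exp(-ds^2 / (2 * sigma_theta^2))
    resp <- matrix(complex(real = 0, imaginary = 0), nr, nc)
    for (s in seq_len(params$n_scales)) {
      f0 <- 1 / (params$min_wavelength * params$mult^(s - 1))
      rad <- exp(-(log(R / f0))^2 / log_bw2)
      rad[1, 1] <- 0
      resp <- resp + fft(FI * (rad * ang), inverse = TRUE) / (nr * nc)
    }
    amp <- Mod(resp)
    better <- amp > best_amp
    best_amp[better] <- amp[better]
    best_resp[better] <- resp[better]
  }
  rng <- diff(range(pixels))
  floor_amp <- noise_floor_frac * as.numeric(quantile(best_amp, 0.99))
  valid <- rng > 0 & best_amp > floor_amp
  phase <- Arg(best_resp)
  phase[!valid] <- NA_real_
  list(phase = phase, amplitude = best_amp, valid = valid)
}

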