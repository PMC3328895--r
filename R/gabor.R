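#' Gabor filter bank
#'
#' Complex exponentials modulated by an elliptical Gaussian:
#' `g(x, y) = exp(i * (2 pi f0 (x cos t0 + y sin t0) + phi)) * gauss(x, y)`
#' with
#' `gauss(x, y) = a * exp(-pi * (a^2 (x cos t0 + y sin t0)^2 +
#'                               b^2 (x sin t0 - y cos t0)^2))`.
#' The default bank holds 16 filters: 4 centre frequencies
#' `{1/16, 1/8, 1/4, 3/8}` cycles/pixel times 4 orientations
#' `{0, 45, 90, 135}` degrees, with `a = b` set for a one-octave
#' half-magnitude frequency bandwidth and `phi = 0`. (The original bank
#' publishes only the counts; the frequencies are declared stand-ins.)
#'
#' @param frequencies 4 centre frequencies `f0` in cycles/pixel.
#' @param orientations_deg 4 orientations `t0` in degrees.
#' @param bandwidth_octaves half-magnitude bandwidth used to derive `a`.
#' @param phase phase offset `phi`.
#' @return A `gabor_bank_spec`.
#' @export
gabor_bank_spec <- function(frequencies = c(1 / 16, 1 / 8, 1 / 4, 3 / 8),
                            orientations_deg = c(0, 45, 90, 135),
                            bandwidth_octaves = 1, phase = 0) {
  stopifnot(all(frequencies > 0))
  # |FT of gauss| halves at (f - f0) = a * sqrt(ln 2 / pi); a one-octave
  # band [f0 - D, f0 + D] with (f0 + D)/(f0 - D) = 2 gives D = f0 / 3
  B <- 2^bandwidth_octaves
  a <- frequencies * (B - 1) / (B + 1) / sqrt(log(2) / pi)
  structure(list(frequencies = frequencies,
                 orientations_deg = orientations_deg,
                 a = a, b = a, phase = phase),
            class = "gabor_bank_spec")
}

#' Complex Gabor kernel on a coordinate grid
#'
#' `x` is the column (horizontal) coordinate and `y` the row (vertical)
#' coordinate, both centred at the filter location.
#'
#' @param x,y numeric coordinates (vectors or matrices of equal shape).
#' @param f0 centre frequency (cycles/pixel), positive.
#' @param theta0 orientation in radians.
#' @param a,b positive shape parameters of the Gaussian envelope.
#' @param phase phase offset `phi`.
#' @return Complex kernel values, same shape as `x`.
#' @export
gabor_kernel <- function(x, y, f0, theta0, a, b, phase = 0) {
  if (a <= 0 || b <= 0 || f0 <= 0) stop("a, b and f0 must be positive")
  u <- x * cos(theta0) + y * sin(theta0)
  v <- x * sin(theta0) - y * cos(theta0)
  env <- a * exp(-pi * (a^2 * u^2 + b^2 * v^2))
  exp(1i * (2 * pi * f0 * u + phase)) * env
}

gabor_response <- function(m, f0, theta0, a, b, phase = 0) {
  h <- nrow(m); w <- ncol(m)
  # kernel sampled on the centred grid, then circularly convolved via FFT
  x <- matrix(rep(fft_freqs(w) * w, each = h), h, w)
  y <- matrix(rep(fft_freqs(h) * h, times = w), h, w)
  ker <- gabor_kernel(x, y, f0, theta0, a, b, phase)
  resp <- stats::fft(stats::fft(m) * stats::fft(ker), inverse = TRUE) / (h * w)
  Mod(resp)
}

#' Gabor texture descriptor (16 x n_bins components)
#'
#' The bank maps the image to 16 magnitude-response images, one per
#' frequency-orientation pair. Each response is summarised by its uniform
#' histogram with nonequidistant (quantile) bins; the 16 histograms are
#' concatenated in frequency-major, orientation-minor order.
#'
#' @param img a [channel_image] or matrix.
#' @param n_bins histogram size, one of 3, 5, 7, 9.
#' @param spec a [gabor_bank_spec()].
#' @param binning optional list of 16 precomputed binnings (training-fold
#'   calibration); default self-calibrates on each response.
#' @return Numeric vector of length `16 * n_bins`.
#' @export
gabor_descriptor <- function(img, n_bins = 9L, spec = gabor_bank_spec(),
                             binning = NULL) {
  if (!n_bins %in% c(3L, 5L, 7L, 9L)) stop("n_bins must be one of 3, 5, 7, 9")
  m <- as_pixel_matrix(img)
  out <- vector("list", length(spec$frequencies) * length(spec$orientations_deg))
  k <- 0L
  for (fi in seq_along(spec$frequencies)) {
    for (oi in seq_along(spec$orientations_deg)) {
      k <- k + 1L
      resp <- gabor_response(m, spec$frequencies[fi],
                             spec$orientations_deg[oi] * pi / 180,
                             spec$a[fi], spec$b[fi], spec$phase)
      bn <- if (!is.null(binning)) binning[[k]] else
        fit_nonequidistant_bins(resp, n_bins)
      out[[k]] <- histogram_descriptor(resp, bn)
    }
  }
  unlist(out)
}
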