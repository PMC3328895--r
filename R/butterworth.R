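#' Butterworth bandpass filter bank
#'
#' The bank is composed of 9 second-order bandpass filters whose passbands
#' jointly cover the whole discrete frequency spectrum `(0, 0.5]`
#' cycles/pixel. Each filter has gain
#' `f(w) = 1 / (1 + ((w - wc) / w0)^(2n))`
#' with centre frequency `wc`, scale `w0` and order `n`; the gain is exactly
#' 1 at `wc` and 0.5 at `wc +/- w0`. The default centre frequencies tile
#' `(0, 0.5]` uniformly with `w0` equal to half the band spacing (a declared
#' stand-in: the original bank parameters are not published).
#'
#' @param n_filters number of bands (default 9).
#' @param order filter order `n` (default 2).
#' @param centres optional centre frequencies in cycles/pixel.
#' @param widths optional per-band scales `w0`.
#' @return A `butterworth_bank_spec` with fields `n_filters`, `order`,
#'   `centres`, `widths`.
#' @export
butterworth_bank_spec <- function(n_filters = 9L, order = 2L,
                                  centres = NULL, widths = NULL) {
  stopifnot(n_filters >= 1L, order >= 1L)
  if (is.null(centres)) centres <- (seq_len(n_filters)) * 0.5 / n_filters
  if (is.null(widths)) widths <- rep(0.25 / n_filters, n_filters)
  stopifnot(length(centres) == n_filters, length(widths) == n_filters,
            all(widths > 0))
  structure(list(n_filters = as.integer(n_filters), order = as.integer(order),
                 centres = centres, widths = widths),
            class = "butterworth_bank_spec")
}

#' Butterworth bandpass gain
#'
#' @param omega frequency (same units as `omega_c`).
#' @param omega_c centre frequency.
#' @param omega_0 scale (half-gain offset); must be positive.
#' @param n filter order.
#' @return Gain value(s) in `(0, 1]`.
#' @export
butterworth_gain <- function(omega, omega_c, omega_0, n = 2L) {
  if (any(omega_0 <= 0)) stop("omega_0 must be positive")
  stopifnot(n >= 1L)
  1 / (1 + ((omega - omega_c) / omega_0)^(2 * n))
}

# DFT sample frequencies in cycles per pixel for length n (fftfreq layout).
fft_freqs <- function(n) {
  k <- 0:(n - 1L)
  ifelse(k <= n %/% 2, k, k - n) / n
}

radial_freq_grid <- function(h, w) {
  fy <- fft_freqs(h); fx <- fft_freqs(w)
  sqrt(outer(fy^2, fx^2, `+`))
}

#' Apply one Butterworth band to an image
#'
#' Multiplies the image spectrum by the radially symmetric 2-D gain of the
#' requested band and inverse-transforms. With `normalise = TRUE` (the
#' default) the band output is rescaled to `[0, 1]` — each band is
#' normalised separately before its histogram is taken.
#'
#' @param img a [channel_image] or matrix.
#' @param band band index in `1..spec$n_filters`.
#' @param spec a [butterworth_bank_spec()].
#' @param normalise rescale output to `[0, 1]`.
#' @return A [channel_image] of the same size.
#' @export
butterworth_band_image <- function(img, band, spec = butterworth_bank_spec(),
                                   normalise = TRUE) {
  m <- as_pixel_matrix(img)
  band <- as.integer(band)
  if (band < 1L || band > spec$n_filters) stop("band out of range")
  gain <- butterworth_gain(radial_freq_grid(nrow(m), ncol(m)),
                           spec$centres[band], spec$widths[band], spec$order)
  out <- Re(stats::fft(stats::fft(m) * gain, inverse = TRUE)) / length(m)
  if (normalise) {
    rng <- range(out)
    out <- if (diff(rng) > 0) (out - rng[1]) / diff(rng) else out * 0
  }
  channel_image(out, if (inherits(img, "channel_image")) img$space_tag else "gray")
}

#' Butterworth band histogram descriptor
#'
#' Normalised band response summarised by a 16-bin nonequidistant
#' histogram. When no calibration `binning` is supplied the quantile bins
#' are fitted on the band response itself (self-calibration); in the
#' cross-validated pipeline the binning is fitted on the training fold.
#'
#' @param img a [channel_image].
#' @param band band index.
#' @param spec a [butterworth_bank_spec()].
#' @param n_bins histogram size (default 16).
#' @param binning optional precomputed [fit_nonequidistant_bins()] result.
#' @return Numeric vector of length `n_bins`.
#' @export
butterworth_descriptor <- function(img, band, spec = butterworth_bank_spec(),
                                   n_bins = 16L, binning = NULL) {
  resp <- butterworth_band_image(img, band, spec)$pixels
  if (is.null(binning)) binning <- fit_nonequidistant_bins(resp, n_bins)
  histogram_descriptor(resp, binning)
}
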