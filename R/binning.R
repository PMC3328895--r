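#' Nonequidistant histogram binning
#'
#' Filter responses concentrate most of their mass in the lowest values, so
#' equal-width histograms waste resolution. The binning used here places the
#' bin edges at empirical quantiles of a calibration sample, so the
#' calibration histogram is uniform ("uniform histogram with nonequidistant
#' bins"): bins are narrow where values concentrate and wide in the tails.
#'
#' @param values numeric calibration sample (e.g. training-set filter
#'   responses).
#' @param n_bins number of bins.
#' @return A `nonequidistant_binning` object with fields `n_bins` and
#'   `edges` (a strictly increasing vector of `n_bins + 1` values spanning
#'   the calibration range).
#' @export
fit_nonequidistant_bins <- function(values, n_bins) {
  stopifnot(n_bins >= 1L)
  values <- values[is.finite(values)]
  if (length(unique(values)) < n_bins)
    stop("need at least `n_bins` distinct calibration values")
  probs <- seq(0, 1, length.out = n_bins + 1L)
  edges <- unname(stats::quantile(values, probs, type = 7))
  # quantile edges can coincide on heavily tied data; nudge to keep them
  # strictly increasing (bin widths stay data-driven)
  eps <- max(1e-12, diff(range(values)) * 1e-12)
  for (i in seq(2L, length(edges)))
    if (edges[i] <= edges[i - 1L]) edges[i] <- edges[i - 1L] + eps
  structure(list(n_bins = as.integer(n_bins), edges = edges),
            class = "nonequidistant_binning")
}

#' Relative-frequency histogram descriptor
#'
#' Bins the pixel values of a channel image with a fitted binning and
#' returns relative frequencies (components sum to 1). Values outside the
#' edge range are clamped into the first/last bin.
#'
#' @param img a [channel_image] or numeric matrix/vector.
#' @param binning a [fit_nonequidistant_bins()] result.
#' @return Numeric vector of length `binning$n_bins` summing to 1.
#' @export
histogram_descriptor <- function(img, binning) {
  stopifnot(inherits(binning, "nonequidistant_binning"))
  x <- as.numeric(if (inherits(img, "channel_image")) img$pixels else img)
  e <- binning$edges
  idx <- findInterval(x, e, rightmost.closed = TRUE)
  idx[idx < 1L] <- 1L
  idx[idx > binning$n_bins] <- binning$n_bins
  counts <- tabulate(idx, nbins = binning$n_bins)
  counts / length(x)
}
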