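#' Colour-space transforms
#'
#' The texture descriptors are computed not only on the grayscale image but
#' also channel-wise in CIE 1976 L*a*b* and in the opponent colour space
#' (red-green, green-red, blue-yellow differences), because the thickest
#' lipid layers show colour fringes that greyscale analysis cannot see.
#'
#' @name colour-spaces
NULL

# ITU-R BT.601 luma weights; declared in the default pipeline config.
GRAY_WEIGHTS <- c(0.299, 0.587, 0.114)

#' Convert an RGB image to grayscale
#'
#' Weighted sum of the three channels with the ITU-R BT.601 luma weights
#' (0.299, 0.587, 0.114). The weights sum to one so the grey axis
#' (R = G = B = c) is a fixed point.
#'
#' @param img an [rgb_image].
#' @param weights length-3 nonnegative weights summing to 1.
#' @return A [channel_image] with `space_tag = "gray"`, values in `[0, 1]`.
#' @export
to_grayscale <- function(img, weights = GRAY_WEIGHTS) {
  stopifnot(inherits(img, "rgb_image"), length(weights) == 3L)
  if (abs(sum(weights) - 1) > 1e-9) stop("gray weights must sum to 1")
  p <- img$pixels
  g <- weights[1] * p[, , 1] + weights[2] * p[, , 2] + weights[3] * p[, , 3]
  channel_image(g, "gray")
}

# sRGB (D65) <-> XYZ matrices, CIE Lab with D65 reference white.
.srgb_to_xyz <- matrix(c(
  0.4124564, 0.3575761, 0.1804375,
  0.2126729, 0.7151522, 0.0721750,
  0.0193339, 0.1191920, 0.9503041), 3L, 3L, byrow = TRUE)
.xyz_to_srgb <- solve(.srgb_to_xyz)
.d65_white <- as.numeric(.srgb_to_xyz %*% c(1, 1, 1))

srgb_decode <- function(u) {
  ifelse(u <= 0.04045, u / 12.92, ((u + 0.055) / 1.055)^2.4)
}
srgb_encode <- function(u) {
  ifelse(u <= 0.0031308, 12.92 * u, 1.055 * u^(1 / 2.4) - 0.055)
}
lab_f <- function(t) {
  d <- 6 / 29
  ifelse(t > d^3, t^(1 / 3), t / (3 * d^2) + 4 / 29)
}
lab_f_inv <- function(t) {
  d <- 6 / 29
  ifelse(t > d, t^3, 3 * d^2 * (t - 4 / 29))
}

#' Convert an RGB image to CIE Lab channels
#'
#' Assumes sRGB primaries and the D65 white point: channels are gamma-decoded,
#' mapped to XYZ and then to L*a*b*. `L` lies in `[0, 100]`; `a` and `b` are
#' finite and near zero on the neutral axis.
#'
#' @param img an [rgb_image].
#' @return A list with [channel_image] elements `L`, `a`, `b`.
#' @export
rgb_to_lab <- function(img) {
  stopifnot(inherits(img, "rgb_image"))
  p <- img$pixels
  dm <- dim(p)[1:2]
  rgb_lin <- srgb_decode(matrix(p, ncol = 3L))
  xyz <- rgb_lin %*% t(.srgb_to_xyz)
  fx <- lab_f(xyz[, 1] / .d65_white[1])
  fy <- lab_f(xyz[, 2] / .d65_white[2])
  fz <- lab_f(xyz[, 3] / .d65_white[3])
  list(
    L = channel_image(matrix(116 * fy - 16, dm[1], dm[2]), "L"),
    a = channel_image(matrix(500 * (fx - fy), dm[1], dm[2]), "a"),
    b = channel_image(matrix(200 * (fy - fz), dm[1], dm[2]), "b")
  )
}

#' Convert Lab values to sRGB
#'
#' Inverse of [rgb_to_lab()] for in-gamut colours; used by the synthetic
#' fringe generator to place colours by their Lab coordinates.
#'
#' @param L,a,b numeric vectors (or matrices of equal shape).
#' @return an `n x 3` matrix (or `H x W x 3` array) of sRGB values,
#'   clipped to `[0, 1]`.
#' @export
lab_to_rgb <- function(L, a, b) {
  dm <- dim(L)
  L <- as.numeric(L); a <- as.numeric(a); b <- as.numeric(b)
  fy <- (L + 16) / 116
  fx <- fy + a / 500
  fz <- fy - b / 200
  xyz <- cbind(lab_f_inv(fx) * .d65_white[1],
               lab_f_inv(fy) * .d65_white[2],
               lab_f_inv(fz) * .d65_white[3])
  rgb_lin <- xyz %*% t(.xyz_to_srgb)
  out <- srgb_encode(pmin(pmax(rgb_lin, 0), 1))
  out <- pmin(pmax(out, 0), 1)
  if (!is.null(dm)) out <- array(out, c(dm, 3L))
  out
}

#' Opponent colour transform specification
#'
#' The opponent channels are differences between a channel and a lowpass
#' filtered version of the opposing channel(s): `RG = R - p * G`,
#' `GR = G - p * R`, `BY = B - p * (R + G)` with `p` a spatial lowpass of
#' unit DC gain (a constant image maps to itself). The filter family and
#' width are configurable; the default is a Gaussian with `sigma = 2` px
#' and reflective borders.
#'
#' @param lowpass_kind currently `"gaussian"`.
#' @param lowpass_sigma spatial scale of the lowpass in pixels.
#' @return An `opponent_spec` object.
#' @export
opponent_spec <- function(lowpass_kind = "gaussian", lowpass_sigma = 2) {
  lowpass_kind <- match.arg(lowpass_kind, "gaussian")
  stopifnot(lowpass_sigma > 0)
  structure(list(lowpass_kind = lowpass_kind, lowpass_sigma = lowpass_sigma),
            class = "opponent_spec")
}

gaussian_kernel_1d <- function(sigma) {
  r <- max(1L, ceiling(4 * sigma))
  k <- exp(-((-r:r)^2) / (2 * sigma^2))
  k / sum(k)          # unit DC gain
}

# Separable convolution with reflective ("symmetric") border handling.
conv2_sep <- function(m, k) {
  r <- (length(k) - 1L) %/% 2L
  pad_reflect <- function(x, r) {
    n <- length(x)
    c(x[pmin(pmax(r:1, 1L), n)], x, x[pmin(pmax(n:(n - r + 1L), 1L), n)])
  }
  conv_vec <- function(x) {
    xp <- pad_reflect(x, r)
    as.numeric(stats::filter(xp, k, sides = 2L))[(r + 1L):(r + length(x))]
  }
  m2 <- apply(m, 2L, conv_vec)
  t(apply(t(m2), 2L, conv_vec))
}

#' Opponent colour channels of an RGB image
#'
#' @param img an [rgb_image].
#' @param spec an [opponent_spec()].
#' @return A list with [channel_image] elements `RG`, `GR`, `BY`.
#' @export
rgb_to_opponent <- function(img, spec = opponent_spec()) {
  stopifnot(inherits(img, "rgb_image"), inherits(spec, "opponent_spec"))
  k <- gaussian_kernel_1d(spec$lowpass_sigma)
  R <- img$pixels[, , 1]; G <- img$pixels[, , 2]; B <- img$pixels[, , 3]
  list(
    RG = channel_image(R - conv2_sep(G, k), "RG"),
    GR = channel_image(G - conv2_sep(R, k), "GR"),
    BY = channel_image(B - conv2_sep(R + G, k), "BY")
  )
}

#' Texture descriptor container
#'
#' A fixed-length numeric vector plus metadata on how it was computed.
#'
#' @param values numeric vector of finite values.
#' @param method texture method identifier.
#' @param space colour space identifier.
#' @param params named list of method parameters.
#' @return A `texture_descriptor` object.
#' @export
texture_descriptor <- function(values, method, space, params = list()) {
  stopifnot(is.numeric(values), all(is.finite(values)))
  structure(list(values = as.numeric(values), method = method, space = space,
                 params = params),
            class = "texture_descriptor")
}

#' @export
print.texture_descriptor <- function(x, ...) {
  cat(sprintf("<texture_descriptor %s/%s, length %d>\n",
              x$method, x$space, length(x$values)))
  invisible(x)
}

#' @export
length.texture_descriptor <- function(x) length(x$values)

channels_for_space <- function(img, space, spec = opponent_spec()) {
  switch(space,
    gray = list(to_grayscale(img)),
    lab = {
      lab <- rgb_to_lab(img)
      list(lab$L, lab$a, lab$b)
    },
    opponent = {
      opp <- rgb_to_opponent(img, spec)
      list(opp$RG, opp$GR, opp$BY)
    },
    stop("unknown colour space: ", space)
  )
}

#' Compute a texture descriptor in a colour space
#'
#' Applies one of the five texture methods channel-wise. For `space = "gray"`
#' the descriptor is the single-channel one; for `"lab"` and `"opponent"`
#' the per-channel descriptors are concatenated in the fixed orders
#' (L, a, b) and (RG, GR, BY), so their length is three times the grayscale
#' length.
#'
#' @param img an [rgb_image].
#' @param method one of `"butterworth"`, `"wavelet"`, `"cooccurrence"`,
#'   `"gmrf"`, `"gabor"`.
#' @param space one of `"gray"`, `"lab"`, `"opponent"`.
#' @param params named list of method parameters: `band` (Butterworth),
#'   `d` (co-occurrence, GMRF), `n_bins` (Gabor; Butterworth optional),
#'   plus optional `binning` (a precomputed [nonequidistant_binning] list,
#'   one per channel, for Butterworth/Gabor) and `spec` overrides.
#' @return A [texture_descriptor].
#' @export
descriptor_in_space <- function(img, method, space, params = list()) {
  method <- match.arg(method,
                      c("butterworth", "wavelet", "cooccurrence", "gmrf",
                        "gabor"))
  space <- match.arg(space, c("gray", "lab", "opponent"))
  chans <- channels_for_space(img, space,
                              params$opponent_spec %||% opponent_spec())
  per_channel <- lapply(seq_along(chans), function(i) {
    ch <- chans[[i]]
    switch(method,
      butterworth = butterworth_descriptor(
        ch, band = params$band %||% 1L,
        spec = params$spec %||% butterworth_bank_spec(),
        n_bins = params$n_bins %||% 16L,
        binning = if (!is.null(params$binning)) params$binning[[i]] else NULL),
      wavelet = wavelet_descriptor(ch),
      cooccurrence = cooccurrence_descriptor(ch, d = params$d %||% 1L,
                                             n_levels = params$n_levels %||% 32L),
      gmrf = gmrf_descriptor(ch, d = params$d %||% 1L),
      gabor = gabor_descriptor(
        ch, n_bins = params$n_bins %||% 9L,
        spec = params$spec %||% gabor_bank_spec(),
        binning = if (!is.null(params$binning)) params$binning[[i]] else NULL)
    )
  })
  texture_descriptor(unlist(per_channel), method, space, params)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
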