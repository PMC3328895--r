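#' Gaussian Markov random field texture model
#'
#' Models the (zero-mean standardised) grey value of each pixel as a linear
#' function of symmetric neighbour-pair sums within a Chebyshev
#' neighbourhood of radius `d` plus Gaussian noise:
#' `X(c) = beta' Q_c + e_c`, where `Q_c` stacks the `4d` sums
#' `X(c + t) + X(c - t)` over the direction offsets `t` of the ring (the
#' same half-ring enumeration as [glcm_offsets()], one per symmetric pair).
#' `beta` is estimated by least squares over the interior pixels (margin
#' `d`). The texture descriptor is the vector of directional residual
#' variances `f_i = mean((X(c) - beta_i * Q_ci)^2)`, length `4d`.
#'
#' @name gmrf-model
NULL

gmrf_design <- function(m, d) {
  h <- nrow(m); w <- ncol(m)
  if (h <= 2 * d || w <= 2 * d) stop("image too small for neighbourhood d = ", d)
  rows <- (d + 1L):(h - d); cols <- (d + 1L):(w - d)
  off <- glcm_offsets(d)
  X <- as.vector(m[rows, cols])
  Q <- vapply(seq_len(nrow(off)), function(k) {
    dr <- off[k, 1]; dc <- off[k, 2]
    as.vector(m[rows + dr, cols + dc] + m[rows - dr, cols - dc])
  }, numeric(length(X)))
  list(X = X, Q = Q)
}

#' Fit a GMRF texture model
#'
#' @param img a [channel_image] or matrix; standardised internally to zero
#'   mean (and unit variance when the image is not constant).
#' @param d Chebyshev neighbourhood radius.
#' @return A `gmrf_model` with fields `beta` (length `4d`), `d`,
#'   `residual_var`, and the standardised image.
#' @export
gmrf_fit <- function(img, d = 1L) {
  m <- as_pixel_matrix(img)
  s <- stats::sd(m)
  if (s == 0) stop("degenerate GMRF model: constant image")
  m <- (m - mean(m)) / s
  dsg <- gmrf_design(m, d)
  qr_ <- qr(dsg$Q)
  if (qr_$rank < ncol(dsg$Q))
    stop("degenerate GMRF model: rank-deficient design")
  beta <- qr.coef(qr_, dsg$X)
  res <- dsg$X - dsg$Q %*% beta
  structure(list(beta = as.numeric(beta), d = as.integer(d),
                 residual_var = mean(res^2), image = m),
            class = "gmrf_model")
}

#' Directional residual variances of a fitted GMRF
#'
#' `f_i = (1/|I|) sum_c (X(c) - beta_i Q_ci)^2` over the interior region,
#' one value per direction `i` (using the jointly fitted `beta_i` against
#' only that direction's neighbour sum).
#'
#' @param img a [channel_image] or matrix (standardised the same way as in
#'   [gmrf_fit()]).
#' @param model a `gmrf_model`.
#' @return Numeric vector of length `4d`.
#' @export
gmrf_directional_variances <- function(img, model) {
  stopifnot(inherits(model, "gmrf_model"))
  m <- as_pixel_matrix(img)
  s <- stats::sd(m)
  if (s == 0) stop("degenerate GMRF model: constant image")
  m <- (m - mean(m)) / s
  dsg <- gmrf_design(m, model$d)
  vapply(seq_along(model$beta), function(i) {
    mean((dsg$X - model$beta[i] * dsg$Q[, i])^2)
  }, numeric(1))
}

#' GMRF texture descriptor (length 4d)
#'
#' @param img a [channel_image] or matrix.
#' @param d Chebyshev neighbourhood radius.
#' @return Numeric vector of length `4d` of directional variances.
#' @export
gmrf_descriptor <- function(img, d = 1L) {
  model <- gmrf_fit(img, d)
  gmrf_directional_variances(img, model)
}
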