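#' Orthonormal Haar pyramid
#'
#' Two-scale standard pyramidal Haar decomposition. One analysis step maps
#' non-overlapping 2 x 2 blocks `[[a, b], [c, d]]` to approximation
#' `LL = (a + b + c + d) / 2` and details `LH`, `HL`, `HH` (orthonormal
#' scaling, so energy is conserved). The step is repeated on `LL1` to give
#' the second scale. Images with odd dimensions are trimmed by one
#' row/column (with a warning).
#'
#' @param img a [channel_image] or matrix, at least 4 x 4.
#' @param n_scales number of scales (default 2).
#' @return A named list of subband matrices `LL1, LH1, HL1, HH1, ...,
#'   LL<n>, LH<n>, HL<n>, HH<n>`.
#' @export
haar_pyramid <- function(img, n_scales = 2L) {
  m <- as_pixel_matrix(img)
  if (nrow(m) < 4L || ncol(m) < 4L) stop("image must be at least 4 x 4")
  out <- list()
  cur <- m
  for (s in seq_len(n_scales)) {
    if (nrow(cur) %% 2L == 1L || ncol(cur) %% 2L == 1L) {
      warning("odd dimensions at scale ", s, "; trimming one row/column")
      cur <- cur[seq_len(nrow(cur) - nrow(cur) %% 2L),
                 seq_len(ncol(cur) - ncol(cur) %% 2L), drop = FALSE]
    }
    if (nrow(cur) < 2L || ncol(cur) < 2L)
      stop("image too small for ", n_scales, " scales")
    odd_r <- seq(1L, nrow(cur), by = 2L); odd_c <- seq(1L, ncol(cur), by = 2L)
    a <- cur[odd_r, odd_c, drop = FALSE]      # top-left of each block
    b <- cur[odd_r, odd_c + 1L, drop = FALSE] # top-right
    c_ <- cur[odd_r + 1L, odd_c, drop = FALSE]   # bottom-left
    d <- cur[odd_r + 1L, odd_c + 1L, drop = FALSE]
    out[[paste0("LL", s)]] <- (a + b + c_ + d) / 2
    out[[paste0("LH", s)]] <- (a - b + c_ - d) / 2  # horizontal detail
    out[[paste0("HL", s)]] <- (a + b - c_ - d) / 2  # vertical detail
    out[[paste0("HH", s)]] <- (a - b - c_ + d) / 2  # diagonal detail
    cur <- out[[paste0("LL", s)]]
  }
  ord <- as.vector(t(outer(c("LL", "LH", "HL", "HH"), seq_len(n_scales),
                           paste0)))
  out[ord]
}

#' Haar wavelet texture descriptor (12 components)
#'
#' Mean and absolute average deviation (`aad = mean(|x - mean(x)|)`) of the
#' input image and of the two approximation subimages `LL1`, `LL2`, plus
#' the energy (`e = mean(x^2)`) of the six detail subimages across the two
#' scales.
#'
#' @param img a [channel_image] or matrix.
#' @return Numeric vector of length 12, ordered
#'   `mu(in), aad(in), mu(LL1), aad(LL1), mu(LL2), aad(LL2),
#'    e(LH1), e(HL1), e(HH1), e(LH2), e(HL2), e(HH2)`.
#' @export
wavelet_descriptor <- function(img) {
  m <- as_pixel_matrix(img)
  pyr <- haar_pyramid(m, 2L)
  aad <- function(x) mean(abs(x - mean(x)))
  energy <- function(x) mean(x^2)
  c(mean(m), aad(m),
    mean(pyr$LL1), aad(pyr$LL1),
    mean(pyr$LL2), aad(pyr$LL2),
    energy(pyr$LH1), energy(pyr$HL1), energy(pyr$HH1),
    energy(pyr$LH2), energy(pyr$HL2), energy(pyr$HH2))
}
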