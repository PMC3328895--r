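#' Region-of-interest extraction
#'
#' Clinicians grade the lipid layer on the bottom part of the iris, the
#' most illuminated area of a well-acquired frame. The ROI is located by
#' maximising the normalised cross-correlation between the luminance
#' component L of the image (in Lab) and a set of illumination-profile
#' templates; the crop under the best template's subtemplate mask is
#' returned.
#'
#' @name roi-extraction
NULL

#' ROI template constructor
#'
#' @param weights `h x w` matrix of illumination-profile weights (must have
#'   nonzero variance).
#' @param subtemplate_mask logical `h x w` matrix marking the crop region
#'   inside the template; must be nonempty and rectangular.
#' @param template_id identifier string.
#' @return A `roi_template` object.
#' @export
roi_template <- function(weights, subtemplate_mask, template_id = "template") {
  stopifnot(is.matrix(weights), is.logical(subtemplate_mask),
            all(dim(weights) == dim(subtemplate_mask)))
  if (stats::sd(weights) == 0) stop("template weights must not be constant")
  if (!any(subtemplate_mask)) stop("subtemplate mask must be nonempty")
  structure(list(weights = weights, subtemplate_mask = subtemplate_mask,
                 template_id = template_id),
            class = "roi_template")
}

#' Normalised cross-correlation score map
#'
#' Pearson-type NCC of a template against every valid placement of an
#' image (valid mode: `(H - h + 1) x (W - w + 1)` placements). Windows with
#' zero variance get score 0 and are flagged in the `"zero_variance"`
#' attribute. Uses running-sum (integral image) window statistics and an
#' FFT cross-correlation for the inner product, so it is exact up to
#' floating point.
#'
#' @param image a [channel_image] or matrix.
#' @param template an [roi_template()] or plain matrix.
#' @return Matrix of NCC values in `[-1, 1]`.
#' @export
normalised_cross_correlation <- function(image, template) {
  m <- as_pixel_matrix(image)
  t_ <- if (inherits(template, "roi_template")) template$weights else template
  h <- nrow(t_); w <- ncol(t_)
  if (h > nrow(m) || w > ncol(m)) stop("template larger than image")
  n <- h * w
  tc <- t_ - mean(t_)
  t_ss <- sum(tc^2)
  if (t_ss == 0) stop("template has zero variance")

  # window sums of m and m^2 via 2-D cumulative sums
  win_sum <- function(x) {
    cs <- apply(apply(x, 2L, cumsum), 1L, cumsum)  # transposed integral image
    cs <- t(cs)
    H <- nrow(x); W <- ncol(x)
    P <- matrix(0, H + 1L, W + 1L)
    P[2:(H + 1L), 2:(W + 1L)] <- cs
    P[(h + 1L):(H + 1L), (w + 1L):(W + 1L)] -
      P[1:(H - h + 1L), (w + 1L):(W + 1L)] -
      P[(h + 1L):(H + 1L), 1:(W - w + 1L)] +
      P[1:(H - h + 1L), 1:(W - w + 1L)]
  }
  S1 <- win_sum(m)
  S2 <- win_sum(m^2)

  # cross term sum(I_window * t_centred) by FFT correlation
  H <- nrow(m); W <- ncol(m)
  tp <- matrix(0, H, W)
  tp[1:h, 1:w] <- tc
  xc <- Re(stats::fft(stats::fft(m) * Conj(stats::fft(tp)), inverse = TRUE)) /
    (H * W)
  cross <- xc[1:(H - h + 1L), 1:(W - w + 1L), drop = FALSE]

  denom_img2 <- S2 - S1^2 / n
  denom_img2[denom_img2 < 0] <- 0          # clamp FP noise
  denom <- sqrt(denom_img2 * t_ss)
  # relative threshold: integral-image cancellation leaves noise of order
  # eps * S2 in the window variance of a constant region
  zero_var <- denom_img2 <= 1e-9 * pmax(S2, .Machine$double.xmin)
  score <- cross / ifelse(zero_var, 1, denom)
  score[zero_var] <- 0
  score[score > 1] <- 1
  score[score < -1] <- -1
  attr(score, "zero_variance") <- zero_var
  score
}

gaussian_band_template <- function(h, w, sigma_frac = 0.18, curvature = 0) {
  r0 <- (h + 1) / 2
  cols <- seq_len(w) - (w + 1) / 2
  centre_rows <- r0 + curvature * (cols^2) / w   # crescent when curvature != 0
  rows <- matrix(seq_len(h), h, w)
  cr <- matrix(centre_rows, h, w, byrow = TRUE)
  exp(-((rows - cr)^2) / (2 * (sigma_frac * h)^2))
}

#' Generate the builtin ROI template set
#'
#' A deterministic stand-in for the unpublished clinical template set:
#' bright horizontal-band and crescent-shaped Gaussian illumination
#' profiles at several scales, each carrying a centred rectangular
#' subtemplate mask covering the brightest part of the band.
#'
#' @param config list with `sizes` (list of `c(h, w)` pairs) and
#'   `curvatures` (numeric; 0 = straight band).
#' @return List of [roi_template()] objects (at least 4 with defaults).
#' @export
generate_templates <- function(config = list()) {
  if (!is.null(config$sizes) && length(config$sizes) == 0L)
    stop("empty template config")
  sizes <- config$sizes %||% list(c(64L, 96L), c(96L, 144L), c(128L, 192L))
  curvatures <- config$curvatures %||% c(0, 6)
  out <- list()
  for (sz in sizes) {
    for (cv in curvatures) {
      h <- sz[1]; w <- sz[2]
      weights <- gaussian_band_template(h, w, curvature = cv)
      mask <- matrix(FALSE, h, w)
      mh <- max(2L, floor(h / 2)); mw <- max(2L, floor(w * 0.8))
      r0 <- floor((h - mh) / 2) + 1L; c0 <- floor((w - mw) / 2) + 1L
      mask[r0:(r0 + mh - 1L), c0:(c0 + mw - 1L)] <- TRUE
      out[[length(out) + 1L]] <- roi_template(
        weights, mask, sprintf("band_h%d_w%d_c%g", h, w, cv))
    }
  }
  out
}

#' Extract the region of interest from an eye image
#'
#' Evaluates the NCC of the Lab luminance channel against every template
#' and returns the crop under the subtemplate mask at the globally best
#' (template, placement) pair. Ties are broken by template order, then
#' row-major placement. Coordinates are 0-based with half-open crop
#' windows.
#'
#' @param img an [rgb_image].
#' @param templates nonempty list of [roi_template()] objects.
#' @return An `roi_result` with fields `crop` (an [rgb_image]), `top_left`
#'   (0-based `(row, col)` of the *subtemplate* crop), `template_top_left`,
#'   `score` and `template_id`.
#' @export
extract_roi <- function(img, templates = generate_templates()) {
  stopifnot(inherits(img, "rgb_image"))
  if (length(templates) == 0L) stop("empty template list")
  L <- rgb_to_lab(img)$L$pixels
  best <- NULL
  for (ti in seq_along(templates)) {
    tpl <- templates[[ti]]
    if (nrow(tpl$weights) > nrow(L) || ncol(tpl$weights) > ncol(L)) next
    sc <- normalised_cross_correlation(L, tpl)
    zv <- attr(sc, "zero_variance")
    if (all(zv)) next
    sc[zv] <- -Inf
    k <- which(t(sc) == max(sc))[1]  # row-major tie-break
    pos <- c((k - 1L) %/% ncol(sc), (k - 1L) %% ncol(sc))  # 0-based (row,col)
    s <- max(sc)
    if (is.null(best) || s > best$score + 1e-12) {
      best <- list(score = s, pos = pos, ti = ti)
    }
  }
  if (is.null(best)) stop("no ROI found: all correlation windows degenerate")
  tpl <- templates[[best$ti]]
  mr <- range(which(rowSums(tpl$subtemplate_mask) > 0))
  mc <- range(which(colSums(tpl$subtemplate_mask) > 0))
  r0 <- best$pos[1] + mr[1] - 1L   # 0-based crop origin
  c0 <- best$pos[2] + mc[1] - 1L
  crop <- rgb_image(img$pixels[(r0 + 1L):(r0 + diff(mr) + 1L),
                               (c0 + 1L):(c0 + diff(mc) + 1L), , drop = FALSE])
  structure(list(crop = crop, top_left = c(r0, c0),
                 template_top_left = best$pos, score = best$score,
                 template_id = tpl$template_id),
            class = "roi_result")
}
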