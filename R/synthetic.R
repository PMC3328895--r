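#' Synthetic interference-pattern generator
#'
#' The clinical image set behind the method is not publicly deposited, so
#' the package ships a seeded generator that emulates the statistical
#' structure of the four Guillon categories: a sparse low-contrast grey
#' meshwork (open meshwork), a denser grey meshwork (closed meshwork),
#' oriented grey waves (wave), and smoothly varying brown/blue colour
#' fringes over a whitish background (colour fringe). The textures are
#' built from thresholded band-limited noise (meshes), phase-jittered
#' sinusoids (waves) and smooth hue fields between two Lab endpoint
#' colours (fringes), all with additive Gaussian pixel noise. They are
#' texture-separable by construction, not photorealistic.
#'
#' @name synthetic-data
NULL

GUILLON_LABELS <- c("open_meshwork", "closed_meshwork", "wave", "colour_fringe")

# fringe endpoint colours in Lab, chosen to be unambiguous under the
# Lab / opponent analyses
FRINGE_BROWN_LAB <- c(55, 15, 30)
FRINGE_BLUE_LAB <- c(55, 5, -35)

#' Category specification for the generator
#'
#' @param label one of `"open_meshwork"`, `"closed_meshwork"`, `"wave"`,
#'   `"colour_fringe"`.
#' @param contrast texture contrast in `[0, 1]` units of intensity.
#' @param spatial_scale characteristic pattern scale in pixels (`>= 2`).
#' @param noise_sd additive Gaussian pixel noise SD.
#' @param base_level background intensity of the grey patterns.
#' @return A `category_spec`.
#' @export
category_spec <- function(label,
                          contrast = NULL, spatial_scale = NULL,
                          noise_sd = 0.02, base_level = NULL) {
  label <- match.arg(label, GUILLON_LABELS)
  defaults <- switch(label,
    # low reflectivity, sparse mesh, faint
    open_meshwork = list(contrast = 0.18, spatial_scale = 9, base_level = 0.30),
    # average reflectivity, compact mesh
    closed_meshwork = list(contrast = 0.30, spatial_scale = 5, base_level = 0.42),
    # grey waves of good visibility
    wave = list(contrast = 0.28, spatial_scale = 12, base_level = 0.45),
    # whitish background carrying colour fringes
    colour_fringe = list(contrast = 0.5, spatial_scale = 14, base_level = 0.75)
  )
  spec <- list(label = label,
               contrast = contrast %||% defaults$contrast,
               spatial_scale = spatial_scale %||% defaults$spatial_scale,
               noise_sd = noise_sd,
               base_level = base_level %||% defaults$base_level)
  stopifnot(spec$contrast >= 0, spec$spatial_scale >= 2)
  structure(spec, class = "category_spec")
}

smooth_noise_field <- function(h, w, sigma) {
  z <- matrix(stats::rnorm(h * w), h, w)
  z <- conv2_sep(z, gaussian_kernel_1d(sigma))
  (z - mean(z)) / stats::sd(z)
}

#' Generate one synthetic category image
#'
#' Deterministic given `(spec, size, seed)`.
#'
#' @param spec a [category_spec()].
#' @param size `c(height, width)`, both `>= 64`.
#' @param seed integer seed.
#' @param orientation_deg wave orientation override (0 = vertical stripes,
#'   90 = horizontal); default drawn from the seed (0 or 90 with jitter).
#' @return An [rgb_image].
#' @export
generate_category_image <- function(spec, size = c(128L, 128L), seed = 1L,
                                    orientation_deg = NULL) {
  stopifnot(inherits(spec, "category_spec"))
  h <- size[1]; w <- size[2]
  if (h < 64L || w < 64L) stop("size must be at least 64 x 64")
  set.seed(seed)
  xs <- matrix(rep(seq_len(w), each = h), h, w)
  ys <- matrix(rep(seq_len(h), times = w), h, w)
  img <- switch(spec$label,
    open_meshwork = ,
    closed_meshwork = {
      # ridges of a band-limited field: bright where the field crosses zero;
      # ridge width (=> mesh density) controlled by the threshold
      fld <- smooth_noise_field(h, w, spec$spatial_scale / 3)
      thr <- if (spec$label == "open_meshwork") 0.22 else 0.55
      mesh <- exp(-(fld / thr)^2)
      g <- spec$base_level + spec$contrast * mesh
      array(rep(g, 3L), c(h, w, 3L))
    },
    wave = {
      ang <- orientation_deg %||%
        (sample(c(0, 90), 1L) + stats::runif(1, -10, 10))
      ang <- ang * pi / 180
      phase <- 2.5 * smooth_noise_field(h, w, spec$spatial_scale)
      carrier <- sin(2 * pi * (xs * cos(ang) + ys * sin(ang)) /
                       spec$spatial_scale + phase)
      g <- spec$base_level + spec$contrast / 2 * carrier
      array(rep(g, 3L), c(h, w, 3L))
    },
    colour_fringe = {
      # mixing field oscillating between the brown and blue Lab endpoints,
      # modulated onto a whitish background
      fld <- smooth_noise_field(h, w, spec$spatial_scale / 2)
      mix <- 0.5 + 0.5 * sin(2.2 * fld)
      amp <- spec$contrast
      L <- (1 - amp) * 95 + amp * (mix * FRINGE_BROWN_LAB[1] +
                                     (1 - mix) * FRINGE_BLUE_LAB[1])
      a <- amp * (mix * FRINGE_BROWN_LAB[2] + (1 - mix) * FRINGE_BLUE_LAB[2])
      b <- amp * (mix * FRINGE_BROWN_LAB[3] + (1 - mix) * FRINGE_BLUE_LAB[3])
      lab_to_rgb(matrix(L, h, w), matrix(a, h, w), matrix(b, h, w))
    })
  img <- img + array(stats::rnorm(h * w * 3L, sd = spec$noise_sd), c(h, w, 3L))
  rgb_image(pmin(pmax(img, 0), 1))
}

#' Generate a stratified synthetic dataset
#'
#' Default class counts mirror the reference clinical set: 29 open
#' meshwork, 29 closed meshwork, 25 wave and 22 colour fringe images
#' (105 in total). Contrast, scale and orientation are jittered per image;
#' everything is deterministic given `seed`.
#'
#' @param class_counts named integer vector of per-class counts, or a
#'   single integer `n_per_class`.
#' @param size image size `c(h, w)`.
#' @param seed integer seed.
#' @return A `synthetic_dataset`: list with `images` (list of
#'   [rgb_image]), `labels` (factor), `seed`, `class_counts`.
#' @export
generate_dataset <- function(class_counts = NULL, size = c(128L, 128L),
                             seed = 1L) {
  if (is.null(class_counts)) {
    class_counts <- c(open_meshwork = 29L, closed_meshwork = 29L,
                      wave = 25L, colour_fringe = 22L)
  } else if (length(class_counts) == 1L && is.null(names(class_counts))) {
    class_counts <- stats::setNames(rep(as.integer(class_counts), 4L),
                                    GUILLON_LABELS)
  }
  stopifnot(all(class_counts >= 1L), all(names(class_counts) %in% GUILLON_LABELS))
  images <- list()
  labels <- character(0)
  i <- 0L
  for (lab in names(class_counts)) {
    for (j in seq_len(class_counts[[lab]])) {
      i <- i + 1L
      img_seed <- (seed * 10000L + i) %% .Machine$integer.max
      set.seed(img_seed)
      jit <- stats::runif(3, c(0.85, 0.8, 0.9), c(1.15, 1.2, 1.1))
      base <- category_spec(lab)
      spec <- category_spec(lab,
                            contrast = base$contrast * jit[1],
                            spatial_scale = max(2, base$spatial_scale * jit[2]),
                            noise_sd = base$noise_sd * jit[3])
      images[[i]] <- generate_category_image(spec, size, seed = img_seed + 1L)
      labels[i] <- lab
    }
  }
  structure(list(images = images,
                 labels = factor(labels, levels = GUILLON_LABELS),
                 seed = seed, class_counts = class_counts),
            class = "synthetic_dataset")
}

#' Generate a synthetic eye frame with a planted bright ROI
#'
#' A dark noisy surround with a bright band-shaped region containing a
#' category texture at a known location, for exercising the ROI stage with
#' ground truth.
#'
#' The planted region's brightness envelope follows the same Gaussian band
#' profile as the builtin ROI templates (see [generate_templates()]), with
#' a category texture modulated on top, so template matching has a ground
#' truth to recover.
#'
#' @param roi_spec list with `top_left` (0-based `c(row, col)`), `height`,
#'   `width` (defaults match the smallest builtin template, 64 x 96), and
#'   optional `category` (default `"wave"`).
#' @param size frame size `c(h, w)`.
#' @param seed integer seed.
#' @return List with `image` (an [rgb_image]) and `top_left` (the 0-based
#'   ground-truth origin of the planted region).
#' @export
generate_eye_image <- function(roi_spec = list(top_left = c(96L, 64L),
                                               height = 64L, width = 96L),
                               size = c(256L, 256L), seed = 1L) {
  h <- size[1]; w <- size[2]
  r0 <- roi_spec$top_left[1]; c0 <- roi_spec$top_left[2]
  rh <- roi_spec$height; rw <- roi_spec$width
  if (r0 < 0 || c0 < 0 || r0 + rh > h || c0 + rw > w)
    stop("ROI region out of frame bounds")
  set.seed(seed)
  frame <- array(stats::rnorm(h * w * 3L, mean = 0.08, sd = 0.02), c(h, w, 3L))
  tex <- generate_category_image(
    category_spec(roi_spec$category %||% "wave"),
    size = c(max(64L, rh), max(64L, rw)), seed = seed + 1L)
  patch <- tex$pixels[seq_len(rh), seq_len(rw), , drop = FALSE]
  prof <- gaussian_band_template(rh, rw)     # same profile as the templates
  bright <- 0.15 + 0.85 * array(rep(prof, 3L), c(rh, rw, 3L))
  frame[(r0 + 1L):(r0 + rh), (c0 + 1L):(c0 + rw), ] <-
    bright * (0.7 + 0.3 * patch)
  list(image = rgb_image(pmin(pmax(frame, 0), 1)),
       top_left = c(r0, c0))
}
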