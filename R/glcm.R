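#' Grey-level co-occurrence matrices and Haralick statistics
#'
#' A GLCM is the joint probability of grey-level pairs at a fixed pixel
#' displacement (distance `d`, orientation `theta`). For a distance `d`,
#' `4d` orientations are enumerated (the half of the Chebyshev ring of
#' radius `d` with angles in `[0, 180)` degrees): d = 1 gives 0, 45, 90 and
#' 135 degrees; d = 2 gives 8 orientations, and so on. Counting is
#' symmetric (each pair is counted in both directions) and matrices are
#' normalised to sum 1.
#'
#' @name glcm-features
NULL

#' Quantise a channel to integer grey levels
#'
#' Uniform range quantisation: the channel range `[min, max]` is split into
#' `n_levels` equal cells giving levels `0 .. n_levels - 1`. A constant
#' image maps entirely to level 0.
#'
#' @param img a [channel_image] or matrix.
#' @param n_levels number of grey levels (default 32).
#' @return Integer matrix of levels in `[0, n_levels)`.
#' @export
quantise_channel <- function(img, n_levels = 32L) {
  m <- as_pixel_matrix(img)
  rng <- range(m)
  if (diff(rng) == 0) return(matrix(0L, nrow(m), ncol(m)))
  q <- as.integer(floor((m - rng[1]) / diff(rng) * n_levels))
  q[q >= n_levels] <- n_levels - 1L
  matrix(q, nrow(m), ncol(m))
}

#' Displacement offsets for a co-occurrence distance
#'
#' Enumerates the `4d` offsets `(drow, dcol)` on the Chebyshev ring of
#' radius `d` with polar angle in `[0, 180)` degrees, ordered by increasing
#' angle (0 degrees = displacement to the right).
#'
#' @param d interpixel distance (Chebyshev radius), `d >= 1`.
#' @return `4d x 2` integer matrix of `(drow, dcol)` offsets.
#' @export
glcm_offsets <- function(d) {
  stopifnot(d >= 1L)
  d <- as.integer(d)
  # walk the half ring counter-clockwise from (0, d): up the right edge,
  # along the top edge leftwards, then down the left edge, stopping just
  # short of 180 degrees; row offsets are negative upwards
  off <- rbind(
    cbind(0L, d),                                        # angle 0
    if (d > 1L) cbind(-(1:(d - 1L)), d),                 # right edge, (0, 45)
    cbind(-d, d:(-d)),                                   # top edge, [45, 135]
    if (d > 1L) cbind(-((d - 1L):1L), -d)                # left edge, (135, 180)
  )
  stopifnot(nrow(off) == 4L * d)
  colnames(off) <- c("drow", "dcol")
  off
}

#' Grey-level co-occurrence matrix
#'
#' @param img quantised integer matrix (see [quantise_channel()]) or a
#'   [channel_image] (quantised internally with `n_levels`).
#' @param d interpixel distance.
#' @param theta orientation in degrees, or an explicit `(drow, dcol)`
#'   offset of length 2.
#' @param n_levels grey-level count `G`; defaults to `max(img) + 1`.
#' @return A `glcmatrix`: a `G x G` matrix summing to 1 with attributes
#'   `d` and `offset`.
#' @export
glcm <- function(img, d = 1L, theta = 0, n_levels = NULL) {
  if (inherits(img, "channel_image") || !is.integer(as.vector(img)[1]) &&
      any(as_pixel_matrix(img) %% 1 != 0)) {
    img <- quantise_channel(img, n_levels %||% 32L)
  }
  m <- as_pixel_matrix(img)
  storage.mode(m) <- "integer"
  G <- n_levels %||% (max(m) + 1L)
  if (length(theta) == 2L) {
    off <- as.integer(theta)
  } else {
    ang <- (theta %% 180) * pi / 180
    off <- c(-round(d * sin(ang)), round(d * cos(ang)))
  }
  dr <- off[1]; dc <- off[2]
  h <- nrow(m); w <- ncol(m)
  r1 <- max(1L, 1L - dr):min(h, h - dr)
  c1 <- max(1L, 1L - dc):min(w, w - dc)
  if (length(r1) < 1L || length(c1) < 1L) stop("no valid pixel pairs")
  i <- m[r1, c1, drop = FALSE]
  j <- m[r1 + dr, c1 + dc, drop = FALSE]
  # symmetric counting: accumulate (i, j) and (j, i)
  idx <- c(i + G * j, j + G * i) + 1L
  counts <- tabulate(idx, nbins = G * G)
  P <- matrix(counts / sum(counts), G, G)
  structure(P, class = c("glcmatrix", "matrix"), d = d, offset = c(dr, dc))
}

#' The 14 Haralick statistics of a co-occurrence matrix
#'
#' Fixed order: angular second moment, contrast, correlation, sum of
#' squares (variance), inverse difference moment, sum average, sum
#' variance, sum entropy, entropy, difference variance, difference entropy,
#' information measures of correlation 1 and 2, maximal correlation
#' coefficient. Entropies use log base 2 with `0 log 0 := 0`. Statistics
#' that require a nonzero marginal variance (correlation, IMC1/2, MCC)
#' return 0 on degenerate matrices, with attribute `degenerate = TRUE`, so
#' descriptors stay finite on constant regions.
#'
#' @param P a normalised `G x G` co-occurrence matrix.
#' @return Numeric vector of length 14 (named).
#' @export
haralick_features <- function(P) {
  P <- unclass(P)
  G <- nrow(P)
  stopifnot(ncol(P) == G, abs(sum(P) - 1) < 1e-6)
  i <- matrix(0:(G - 1L), G, G)
  j <- t(i)
  px <- rowSums(P); py <- colSums(P)
  lvl <- 0:(G - 1L)
  mux <- sum(lvl * px); muy <- sum(lvl * py)
  sdx <- sqrt(sum((lvl - mux)^2 * px)); sdy <- sqrt(sum((lvl - muy)^2 * py))
  log2z <- function(x) ifelse(x > 0, log2(x), 0)
  ent <- function(p) -sum(p * log2z(p))

  # p_{x+y}(k), k = 0..2G-2 and p_{x-y}(k), k = 0..G-1
  sums_idx <- as.vector(i + j)
  pxy_sum <- as.vector(tapply(as.vector(P), sums_idx, sum))
  diff_idx <- as.vector(abs(i - j))
  pxy_diff <- as.vector(tapply(as.vector(P), diff_idx, sum))
  ks <- sort(unique(sums_idx)); kd <- sort(unique(diff_idx))

  degenerate <- (sdx == 0 || sdy == 0)

  asm <- sum(P^2)
  contrast <- sum((i - j)^2 * P)
  correlation <- if (degenerate) 0 else sum((i - mux) * (j - muy) * P) / (sdx * sdy)
  variance <- sum((i - mux)^2 * P)      # sum of squares about marginal mean
  idm <- sum(P / (1 + (i - j)^2))
  sum_avg <- sum(ks * pxy_sum)
  sum_ent <- ent(pxy_sum)
  sum_var <- sum((ks - sum_avg)^2 * pxy_sum)
  entropy <- ent(P)
  diff_avg <- sum(kd * pxy_diff)
  diff_var <- sum((kd - diff_avg)^2 * pxy_diff)
  diff_ent <- ent(pxy_diff)

  hx <- ent(px); hy <- ent(py)
  hxy1 <- -sum(P * log2z(px[row(P)] * py[col(P)]))
  hxy2 <- -sum(outer(px, py) * log2z(outer(px, py)))
  imc1 <- if (degenerate || max(hx, hy) == 0) 0 else (entropy - hxy1) / max(hx, hy)
  imc2 <- if (degenerate) 0 else sqrt(max(0, 1 - exp(-2 * log(2) * (hxy2 - entropy))))

  mcc <- if (degenerate) 0 else {
    nz <- px > 0 & py > 0
    Q <- matrix(0, G, G)
    Psub <- P[nz, nz, drop = FALSE]
    Q[nz, nz] <- (Psub / px[nz]) %*% (t(Psub) / py[nz])
    ev <- sort(Re(eigen(Q, only.values = TRUE)$values), decreasing = TRUE)
    if (length(ev) < 2L || ev[2] < 0) 0 else sqrt(ev[2])
  }

  out <- c(asm = asm, contrast = contrast, correlation = correlation,
           variance = variance, idm = idm, sum_average = sum_avg,
           sum_variance = sum_var, sum_entropy = sum_ent, entropy = entropy,
           difference_variance = diff_var, difference_entropy = diff_ent,
           imc1 = imc1, imc2 = imc2, mcc = mcc)
  attr(out, "degenerate") <- degenerate
  out
}

#' Co-occurrence texture descriptor (28 components)
#'
#' Computes the 14 Haralick statistics on each of the `4d` matrices at
#' distance `d` and summarises them by their mean and range (max - min)
#' across matrices.
#'
#' @param img a [channel_image] or matrix.
#' @param d interpixel distance, `d >= 1`.
#' @param n_levels grey levels for quantisation (default 32).
#' @return Numeric vector of length 28: 14 means then 14 ranges.
#' @export
cooccurrence_descriptor <- function(img, d = 1L, n_levels = 32L) {
  stopifnot(d >= 1L)
  q <- quantise_channel(img, n_levels)
  off <- glcm_offsets(d)
  stats <- vapply(seq_len(nrow(off)), function(k) {
    haralick_features(glcm(q, d = d, theta = off[k, ], n_levels = n_levels))
  }, numeric(14L))
  unname(c(rowMeans(stats), apply(stats, 1L, max) - apply(stats, 1L, min)))
}
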