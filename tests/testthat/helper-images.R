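# shared fixture builders (all in-code; no stored binaries)

random_rgb <- function(h = 16, w = 16, seed = 1) {
  set.seed(seed)
  rgb_image(array(runif(h * w * 3), c(h, w, 3)))
}

constant_rgb <- function(value, h = 8, w = 8) {
  rgb_image(array(value, c(h, w, 3)))
}

# direct double-loop Pearson NCC oracle
ncc_oracle <- function(img, tpl) {
  h <- nrow(tpl); w <- ncol(tpl)
  out <- matrix(0, nrow(img) - h + 1, ncol(img) - w + 1)
  for (r in seq_len(nrow(out))) {
    for (c in seq_len(ncol(out))) {
      win <- img[r:(r + h - 1), c:(c + w - 1)]
      out[r, c] <- stats::cor(as.vector(win), as.vector(tpl))
    }
  }
  out
}

# conditional-autoregressive field with one horizontal interaction beta:
# spectral density 1/(1 - 2 beta cos(wx)); least squares on the symmetric
# neighbour sums is consistent for this construction
car_field_horizontal <- function(h, w, beta, seed) {
  set.seed(seed)
  z <- matrix(rnorm(h * w), h, w)
  wx <- 2 * pi * outer(rep(1, h), 0:(w - 1)) / w
  lam <- 1 - 2 * beta * cos(wx)
  stopifnot(all(lam > 0))
  Re(stats::fft(stats::fft(z) / sqrt(lam), inverse = TRUE)) / (h * w)
}
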