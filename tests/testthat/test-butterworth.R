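test_that("gain formula hits its fixed points", {
  expect_equal(butterworth_gain(0.2, 0.2, 0.05, 2), 1)
  for (n in 1:4) {
    expect_equal(butterworth_gain(0.25, 0.2, 0.05, n), 0.5)
    expect_equal(butterworth_gain(0.15, 0.2, 0.05, n), 0.5)
  }
  # n = 2, offset of two scales: 1 / (1 + 2^4)
  expect_equal(butterworth_gain(0.3, 0.2, 0.05, 2), 1 / 17)
  expect_error(butterworth_gain(0.1, 0.2, 0), "positive")
})

test_that("band image matches a direct spatial-convolution oracle", {
  set.seed(9)
  m <- matrix(runif(32 * 32), 32, 32)
  spec <- butterworth_bank_spec()
  out <- butterworth_band_image(m, 3, spec, normalise = FALSE)$pixels
  ff <- tearfilm:::fft_freqs(32)
  gain <- butterworth_gain(sqrt(outer(ff^2, ff^2, `+`)),
                           spec$centres[3], spec$widths[3], spec$order)
  ker <- Re(stats::fft(gain, inverse = TRUE)) / (32 * 32)
  oracle <- matrix(0, 32, 32)
  for (r in 1:32) for (c_ in 1:32) {
    s <- 0
    for (i in 1:32) for (j in 1:32)
      s <- s + m[i, j] * ker[((r - i) %% 32) + 1, ((c_ - j) %% 32) + 1]
    oracle[r, c_] <- s
  }
  expect_lt(max(abs(out - oracle)), 1e-6)
})

test_that("bandpass kills DC and passes the centre frequency", {
  # custom high-order band whose DC gain is < 1e-6 by construction
  spec4 <- butterworth_bank_spec(n_filters = 1L, order = 4L,
                                 centres = 0.25, widths = 0.025)
  out <- butterworth_band_image(matrix(0.7, 16, 16), 1, spec4,
                                normalise = FALSE)$pixels
  expect_lt(max(abs(out)), 1e-6)
  # pure on-grid sinusoid at a band centre passes with unit gain
  spec <- butterworth_bank_spec()
  wc <- spec$centres[3]                      # 3/18 cpp; on-grid for 48 cols
  x <- matrix(rep(0:47, each = 48), 48, 48)
  sig <- sin(2 * pi * wc * x)
  out2 <- butterworth_band_image(sig, 3, spec, normalise = FALSE)$pixels
  expect_lt(max(abs(out2 - sig)), 1e-6)
})

test_that("bank spec and descriptor obey their contracts", {
  spec <- butterworth_bank_spec()
  expect_equal(spec$n_filters, 9L)
  expect_equal(spec$order, 2L)
  expect_equal(max(spec$centres), 0.5)
  img <- channel_image(matrix(runif(64 * 64), 64, 64))
  for (band in c(1, 5, 9)) {
    d <- butterworth_descriptor(img, band)
    expect_length(d, 16)
    expect_equal(sum(d), 1, tolerance = 1e-9)
  }
  expect_error(butterworth_band_image(img, 10), "range")
  # normalised band output stays in [0, 1]
  b <- butterworth_band_image(img, 4)$pixels
  expect_gte(min(b), 0)
  expect_lte(max(b), 1)
})
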