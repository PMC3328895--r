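test_that("grayscale conversion fixes the grey axis and [0,1] range", {
  expect_equal(to_grayscale(constant_rgb(1))$pixels,
               matrix(1, 8, 8))
  expect_equal(to_grayscale(constant_rgb(0))$pixels,
               matrix(0, 8, 8))
  for (c_ in c(0.25, 0.5, 0.9)) {
    expect_equal(to_grayscale(constant_rgb(c_))$pixels,
                 matrix(c_, 8, 8), tolerance = 1e-12)
  }
  g <- to_grayscale(random_rgb(seed = 3))
  expect_true(all(g$pixels >= 0 & g$pixels <= 1))
})

test_that("Lab conversion hits the white point and neutral axis", {
  w <- rgb_to_lab(constant_rgb(1))
  expect_equal(w$L$pixels[1, 1], 100, tolerance = 1e-6)
  expect_lt(abs(w$a$pixels[1, 1]), 0.5)
  expect_lt(abs(w$b$pixels[1, 1]), 0.5)
  b <- rgb_to_lab(constant_rgb(0))
  expect_equal(b$L$pixels[1, 1], 0, tolerance = 1e-9)
  g <- rgb_to_lab(constant_rgb(0.5))
  expect_lt(abs(g$a$pixels[1, 1]), 1e-9)
  expect_lt(abs(g$b$pixels[1, 1]), 1e-9)
})

test_that("Lab round-trip is exact on an in-gamut RGB grid", {
  vals <- seq(0.05, 0.95, length.out = 5)
  grid <- as.matrix(expand.grid(vals, vals, vals))   # 125 in-gamut colours
  img <- rgb_image(array(grid, c(25, 5, 3)))
  lab <- rgb_to_lab(img)
  back <- lab_to_rgb(lab$L$pixels, lab$a$pixels, lab$b$pixels)
  expect_lt(max(abs(back - img$pixels)), 1e-6)
})

test_that("Lab agrees with the grDevices reference converter", {
  # independent oracle; small tolerance covers its different adaptation
  rgbs <- rbind(c(0.2, 0.5, 0.8), c(0.9, 0.1, 0.3), c(0.4, 0.4, 0.1))
  img <- rgb_image(array(rbind(rgbs, rgbs), c(3, 2, 3)))  # 3 x 2 image
  ours <- rgb_to_lab(img)
  ref <- grDevices::convertColor(rgbs, "sRGB", "Lab")
  got <- cbind(ours$L$pixels[, 1], ours$a$pixels[, 1], ours$b$pixels[, 1])
  expect_lt(max(abs(got - ref)), 0.5)
})

test_that("opponent transform honours linearity and the constant image", {
  spec <- opponent_spec()
  z <- rgb_to_opponent(constant_rgb(0), spec)
  expect_equal(z$RG$pixels, matrix(0, 8, 8))
  expect_equal(z$BY$pixels, matrix(0, 8, 8))
  cimg <- rgb_to_opponent(constant_rgb(0.4, 16, 16), spec)
  # unit-DC lowpass maps constant c to c: RG = GR = 0, BY = c - 2c = -c
  expect_equal(cimg$RG$pixels, matrix(0, 16, 16), tolerance = 1e-12)
  expect_equal(cimg$GR$pixels, matrix(0, 16, 16), tolerance = 1e-12)
  expect_equal(cimg$BY$pixels, matrix(-0.4, 16, 16), tolerance = 1e-12)

  i1 <- random_rgb(12, 12, seed = 4)$pixels
  i2 <- random_rgb(12, 12, seed = 5)$pixels
  mix <- rgb_image(pmin(pmax(0.3 * i1 + 0.5 * i2, 0), 1))
  o_mix <- rgb_to_opponent(mix, spec)
  o1 <- rgb_to_opponent(rgb_image(i1), spec)
  o2 <- rgb_to_opponent(rgb_image(i2), spec)
  for (ch in c("RG", "GR", "BY")) {
    expect_equal(o_mix[[ch]]$pixels,
                 0.3 * o1[[ch]]$pixels + 0.5 * o2[[ch]]$pixels,
                 tolerance = 1e-9)
  }
})

test_that("opponent delta image reproduces the negated lowpass kernel", {
  # single nonzero G pixel at the centre: RG = -p (the kernel) centred there
  h <- 33; w <- 33
  a <- array(0, c(h, w, 3))
  a[17, 17, 2] <- 1
  opp <- rgb_to_opponent(rgb_image(a), opponent_spec(lowpass_sigma = 2))
  k1 <- tearfilm:::gaussian_kernel_1d(2)
  k2 <- outer(k1, k1)
  r <- (length(k1) - 1) / 2
  got <- opp$RG$pixels[(17 - r):(17 + r), (17 - r):(17 + r)]
  expect_equal(got, -k2, tolerance = 1e-12)
})

test_that("descriptor concatenation order and lengths are stable", {
  img <- random_rgb(40, 40, seed = 8)
  d_gray <- descriptor_in_space(img, "cooccurrence", "gray", list(d = 1))
  expect_length(d_gray, 28)
  d_lab <- descriptor_in_space(img, "cooccurrence", "lab", list(d = 1))
  expect_length(d_lab, 84)
  d_opp <- descriptor_in_space(img, "butterworth", "opponent",
                               list(band = 2, n_bins = 16))
  expect_length(d_opp, 48)
  # stability: identical inputs give identical descriptors
  expect_identical(d_lab$values,
                   descriptor_in_space(img, "cooccurrence", "lab",
                                       list(d = 1))$values)
  # lab = concat(L, a, b) in that order
  lab <- rgb_to_lab(img)
  expect_equal(d_lab$values[1:28], cooccurrence_descriptor(lab$L, 1))
  expect_equal(d_lab$values[29:56], cooccurrence_descriptor(lab$a, 1))
  expect_error(descriptor_in_space(img, "sift", "gray"), "arg")
  expect_error(descriptor_in_space(img, "cooccurrence", "hsv"), "arg")
})
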