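test_that("generation is deterministic per seed and varies across seeds", {
  spec <- category_spec("wave")
  a <- generate_category_image(spec, c(64, 64), seed = 5)
  b <- generate_category_image(spec, c(64, 64), seed = 5)
  expect_identical(a$pixels, b$pixels)
  c_ <- generate_category_image(spec, c(64, 64), seed = 6)
  expect_false(identical(a$pixels, c_$pixels))
  expect_error(generate_category_image(spec, c(32, 32)), "64")
})

test_that("wave images have their spectral peak at the stated frequency", {
  spec <- category_spec("wave", noise_sd = 0.005)
  img <- generate_category_image(spec, c(128, 128), seed = 3,
                                 orientation_deg = 0)
  g <- to_grayscale(img)$pixels
  sp <- Mod(stats::fft(g - mean(g)))^2
  peak <- which(sp == max(sp), arr.ind = TRUE)[1, ]
  # orientation 0: variation along columns at period spatial_scale
  fx <- tearfilm:::fft_freqs(128)[peak[2]]
  fy <- tearfilm:::fft_freqs(128)[peak[1]]
  expect_lt(abs(abs(fx) - 1 / spec$spatial_scale), 0.02)
  expect_lt(abs(fy), 0.05)   # phase jitter spreads a little energy in y
})

test_that("colour fringes carry more chroma than every grey category", {
  chroma <- function(img) {
    lab <- rgb_to_lab(img)
    mean(sqrt(lab$a$pixels^2 + lab$b$pixels^2))
  }
  for (seed in 1:3) {
    fr <- chroma(generate_category_image(category_spec("colour_fringe"),
                                         c(64, 64), seed = seed))
    greys <- vapply(c("open_meshwork", "closed_meshwork", "wave"),
                    function(l) chroma(generate_category_image(
                      category_spec(l), c(64, 64), seed = seed)), 1)
    expect_gt(fr, max(greys))
  }
})

test_that("default dataset mirrors the reference class counts", {
  ds <- generate_dataset(size = c(64L, 64L), seed = 2)
  expect_length(ds$images, 105)
  expect_equal(as.vector(table(ds$labels)), c(29, 29, 25, 22))
  small <- generate_dataset(2, size = c(64L, 64L), seed = 2)
  expect_length(small$images, 8)
  # different seeds: same label sequence, different pixels
  ds2 <- generate_dataset(2, size = c(64L, 64L), seed = 3)
  expect_identical(small$labels, ds2$labels)
  expect_false(identical(small$images[[1]]$pixels, ds2$images[[1]]$pixels))
  # same seed twice: identical
  ds3 <- generate_dataset(2, size = c(64L, 64L), seed = 2)
  expect_identical(small$images[[5]]$pixels, ds3$images[[5]]$pixels)
})

test_that("eye frames plant the brightest window at the ground truth", {
  eye <- generate_eye_image(seed = 2)
  g <- to_grayscale(eye$image)$pixels
  h <- 64; w <- 96
  # exhaustive window-mean scan via integral image
  P <- matrix(0, nrow(g) + 1, ncol(g) + 1)
  P[-1, -1] <- t(apply(apply(g, 2, cumsum), 1, cumsum))
  best <- -Inf; arg <- NULL
  for (r in 1:(nrow(g) - h + 1)) {
    for (c_ in 1:(ncol(g) - w + 1)) {
      s <- P[r + h, c_ + w] - P[r, c_ + w] - P[r + h, c_] + P[r, c_]
      if (s > best) { best <- s; arg <- c(r - 1, c_ - 1) }
    }
  }
  expect_equal(arg, eye$top_left)
  # extract_roi recovers the planted location
  res <- extract_roi(eye$image)
  expect_lte(max(abs(res$template_top_left - eye$top_left)), 2)
  # determinism
  eye2 <- generate_eye_image(seed = 2)
  expect_identical(eye$image$pixels, eye2$image$pixels)
  expect_error(generate_eye_image(list(top_left = c(250, 0), height = 64,
                                       width = 96), c(256, 256)),
               "bounds")
})
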