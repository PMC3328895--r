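test_that("offset enumeration yields 4d orientations on the half ring", {
  for (d in 1:10) {
    off <- glcm_offsets(d)
    expect_equal(nrow(off), 4 * d)
    expect_equal(max(pmax(abs(off[, 1]), abs(off[, 2]))), d)  # on the ring
    # angles all in [0, 180), no duplicates
    ang <- atan2(-off[, 1], off[, 2]) * 180 / pi
    expect_true(all(ang >= 0 & ang < 180))
    expect_equal(anyDuplicated(ang), 0)
  }
  expect_equal(glcm_offsets(1),
               matrix(c(0L, 1L, -1L, 1L, -1L, 0L, -1L, -1L), 4, 2,
                      byrow = TRUE, dimnames = list(NULL, c("drow", "dcol"))))
})

test_that("small-matrix GLCMs match hand enumeration", {
  m <- matrix(c(0L, 0L, 1L, 1L), 2, 2, byrow = TRUE)
  P <- glcm(m, d = 1, theta = 0, n_levels = 2)
  # two horizontal pairs (0,0) and (1,1), counted symmetrically
  expect_equal(unclass(P)[, ], matrix(c(0.5, 0, 0, 0.5), 2, 2), ignore_attr = TRUE)
  expect_equal(sum(P), 1)
  # constant image: one cell of mass 1
  Pc <- glcm(matrix(0L, 4, 4), d = 1, theta = 0, n_levels = 2)
  expect_equal(unclass(Pc)[1, 1], 1)
})

test_that("Haralick statistics match brute-force formulas", {
  # constant-image GLCM: single cell of mass 1
  Pc <- glcm(matrix(0L, 4, 4), d = 1, theta = 0, n_levels = 4)
  hc <- haralick_features(Pc)
  expect_equal(unname(hc["asm"]), 1)
  expect_equal(unname(hc["entropy"]), 0)
  expect_equal(unname(hc["contrast"]), 0)
  expect_true(attr(hc, "degenerate"))

  # checkerboard, d=1, horizontal: all mass on |i-j| = 1 with 2 levels
  cb <- outer(1:6, 1:6, function(i, j) (i + j) %% 2L)
  hcb <- haralick_features(glcm(cb, d = 1, theta = 0, n_levels = 2))
  expect_equal(unname(hcb["contrast"]), 1)

  # random matrix: entropy against the direct sum
  set.seed(11)
  M <- matrix(runif(64), 8, 8)
  M <- (M + t(M)); M <- M / sum(M)
  h <- haralick_features(M)
  expect_equal(unname(h["entropy"]), -sum(M * log2(M)), tolerance = 1e-10)
  expect_equal(unname(h["asm"]), sum(M^2), tolerance = 1e-12)
})

test_that("haralick correlation stays in [-1, 1] on random images", {
  set.seed(12)
  for (i in 1:5) {
    q <- matrix(sample(0:7, 400, replace = TRUE), 20, 20)
    h <- haralick_features(glcm(q, d = 1, theta = 45, n_levels = 8))
    expect_gte(unname(h["correlation"]), -1)
    expect_lte(unname(h["correlation"]), 1)
    expect_gte(unname(h["imc2"]), 0)
    expect_lte(unname(h["mcc"]), 1 + 1e-9)
  }
})

test_that("co-occurrence descriptor has 28 features and sane ranges", {
  set.seed(13)
  img <- channel_image(matrix(runif(60 * 60), 60, 60))
  for (d in c(1, 2, 5)) {
    expect_length(cooccurrence_descriptor(img, d), 28)
  }
  # constant image: all 4d matrices identical -> ranges all 0
  dc <- cooccurrence_descriptor(matrix(0.5, 20, 20), 2)
  expect_equal(dc[15:28], rep(0, 14))
})
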