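test_that("NCC matches the brute-force Pearson oracle everywhere", {
  set.seed(5)
  img <- matrix(runif(16 * 16), 16, 16)
  tpl <- matrix(runif(25), 5, 5)
  sc <- normalised_cross_correlation(img, tpl)
  expect_lt(max(abs(sc - ncc_oracle(img, tpl))), 1e-10)
  # larger FFT-path instance against the same oracle
  set.seed(6)
  img64 <- matrix(runif(64 * 64), 64, 64)
  tpl9 <- matrix(runif(81), 9, 9)
  expect_lt(max(abs(normalised_cross_correlation(img64, tpl9) -
                      ncc_oracle(img64, tpl9))), 1e-6)
})

test_that("NCC self- and anti-correlation and affine invariance", {
  set.seed(7)
  img <- matrix(runif(20 * 20), 20, 20)
  sub <- img[4:10, 5:12]
  sc <- normalised_cross_correlation(img, sub)
  expect_equal(sc[4, 5], 1, tolerance = 1e-9)
  expect_equal(max(sc), 1, tolerance = 1e-9)
  neg <- normalised_cross_correlation(img, -2 * sub + 3)
  expect_equal(neg[4, 5], -1, tolerance = 1e-9)
  # invariance to positive affine maps of the image
  sc2 <- normalised_cross_correlation(4.2 * img + 0.7, sub)
  expect_lt(max(abs(sc - sc2)), 1e-8)
})

test_that("NCC flags zero-variance windows and rejects oversized templates", {
  img <- matrix(0.5, 12, 12)
  img[1:3, 1:3] <- matrix(runif(9), 3, 3)   # one varying corner
  tpl <- matrix(runif(9), 3, 3)
  sc <- normalised_cross_correlation(img, tpl)
  zv <- attr(sc, "zero_variance")
  expect_true(any(zv))
  expect_true(all(sc[zv] == 0))
  expect_error(normalised_cross_correlation(matrix(1:4, 2, 2),
                                            matrix(runif(9), 3, 3)),
               "larger")
})

test_that("builtin template set is deterministic and well-formed", {
  t1 <- generate_templates()
  t2 <- generate_templates()
  expect_gte(length(t1), 4)
  expect_identical(t1, t2)
  for (tpl in t1) {
    expect_s3_class(tpl, "roi_template")
    expect_gt(stats::sd(tpl$weights), 0)
    expect_true(any(tpl$subtemplate_mask))
  }
  expect_error(generate_templates(list(sizes = list())), "empty")
  expect_error(roi_template(matrix(1, 4, 4), matrix(TRUE, 4, 4)), "constant")
})

test_that("extract_roi recovers a planted bright band", {
  templates <- generate_templates()
  eye <- generate_eye_image(seed = 2)
  res <- extract_roi(eye$image, templates)
  expect_lte(max(abs(res$template_top_left - eye$top_left)), 1)
  expect_gt(res$score, 0.9)
  # constant image: every window degenerate -> explicit error
  expect_error(extract_roi(constant_rgb(0.5, 128, 128), templates),
               "no ROI")
  # template too large for the image errors at use time
  big <- generate_templates(list(sizes = list(c(300L, 300L))))
  expect_error(extract_roi(constant_rgb(0.5, 128, 128), big))
})

test_that("image equal to a padded template yields the subtemplate crop", {
  templates <- generate_templates()
  tpl <- templates[[1]]
  h <- nrow(tpl$weights); w <- ncol(tpl$weights)
  frame <- matrix(0, h + 40, w + 40)
  frame[21:(20 + h), 21:(20 + w)] <- tpl$weights
  img <- rgb_image(array(rep(frame, 3), c(nrow(frame), ncol(frame), 3)))
  res <- extract_roi(img, templates[1])
  expect_equal(res$template_top_left, c(20, 20))
  mr <- range(which(rowSums(tpl$subtemplate_mask) > 0))
  mc <- range(which(colSums(tpl$subtemplate_mask) > 0))
  expect_equal(res$top_left, c(20 + mr[1] - 1, 20 + mc[1] - 1))
  expect_equal(dim(res$crop$pixels)[1:2], c(diff(mr) + 1, diff(mc) + 1))
})
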