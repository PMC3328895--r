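separable_dataset <- function(n_per_class = 12, p = 6, sep = 6, seed = 1) {
  set.seed(seed)
  classes <- paste0("k", 1:4)
  X <- do.call(rbind, lapply(seq_along(classes), function(k) {
    mu <- rep(0, p); mu[k %% p + 1] <- sep
    matrix(rnorm(n_per_class * p), n_per_class, p) +
      matrix(mu, n_per_class, p, byrow = TRUE)
  }))
  labelled_dataset(X, rep(classes, each = n_per_class))
}

test_that("stratified folds partition n and balance class proportions", {
  ds <- separable_dataset(n_per_class = 13, seed = 2)
  set.seed(5)
  fid <- tearfilm:::stratified_fold_ids(ds$y, 10)
  expect_equal(length(fid), 52)
  expect_equal(sort(unique(fid)), 1:10)
  # per-fold class counts within one sample of the ideal proportion
  for (cl in levels(ds$y)) {
    per_fold <- tabulate(fid[ds$y == cl], 10)
    expect_lte(max(per_fold) - min(per_fold), 1)
  }
})

test_that("well-separated classes reach high CV accuracy", {
  ds <- separable_dataset(seed = 3)
  res <- crossval_accuracy(ds, "SVM", k = 10, seed = 42)
  expect_gte(res$accuracy, 95)
  expect_equal(sum(res$fold_sizes), 48)
})

test_that("label permutation drops accuracy to chance level", {
  ds <- separable_dataset(seed = 4)
  accs <- vapply(1:3, function(s) {
    set.seed(100 + s)
    yp <- sample(ds$y)
    crossval_accuracy(labelled_dataset(ds$X, yp), "SVM", k = 10,
                      seed = 42)$accuracy
  }, 1)
  expect_true(all(accs >= 5 & accs <= 45))
  expect_gte(mean(accs), 15)
  expect_lte(mean(accs), 35)
})

test_that("CV is deterministic given data and seed", {
  ds <- separable_dataset(seed = 5)
  r1 <- crossval_accuracy(ds, "RF", k = 5, seed = 77)
  r2 <- crossval_accuracy(ds, "RF", k = 5, seed = 77)
  expect_identical(r1, r2)
  expect_error(crossval_accuracy(ds, "RF", k = 1), "at least 2")
})

test_that("accuracy tables carry exact row means and reject bad input", {
  vals <- rbind(SVM = c(80.00, 84.76, 87.62, 89.52, 91.43, 90.48, 92.38))
  tab <- as_accuracy_table(vals)
  expect_equal(round(unclass(tab)["SVM", "Avg."], 2), 88.03)
  single <- as_accuracy_table(rbind(NB = 75))
  expect_equal(unname(unclass(single)[1, "Avg."]), 75)
  bad <- rbind(a = c(50, NA))
  expect_error(as_accuracy_table(bad), "missing")
  expect_error(as_accuracy_table(rbind(a = c(50, 120))), "\\[0, 100\\]")
})

test_that("greater class separation does not hurt median SVM accuracy", {
  meds <- vapply(c(0.5, 2, 6), function(sep) {
    accs <- vapply(1:5, function(s) {
      crossval_accuracy(separable_dataset(sep = sep, seed = s), "SVM",
                        k = 5, seed = 42)$accuracy
    }, 1)
    stats::median(accs)
  }, 1)
  expect_true(all(diff(meds) >= 0))
})
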