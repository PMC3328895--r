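#' Pipeline configuration and orchestration
#'
#' @name pipeline
NULL

#' Default pipeline configuration
#'
#' A declarative document of every tunable parameter; CLI flags and
#' function arguments override it, and each run's resolved configuration
#' is embedded in its output.
#'
#' @param ... named overrides of top-level keys.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    colour = list(gray_weights = GRAY_WEIGHTS, white_point = "D65",
                  lowpass_kind = "gaussian", lowpass_sigma = 2),
    butterworth = list(n_filters = 9L, order = 2L, n_bins = 16L),
    glcm = list(n_levels = 32L),
    gabor = list(n_bins_set = c(3L, 5L, 7L, 9L)),
    classifiers = c("NB", "LMT", "RT", "RF", "SVM"),
    cv = list(k = 10L, seed = 20120405L),
    stats = list(alpha = 0.05, lilliefors_n_mc = 10000L),
    conditions = list(butterworth = 1:9, cooccurrence = 1:7, gmrf = 1:10,
                      gabor = c(3L, 5L, 7L, 9L))
  )
  overrides <- list(...)
  cfg[names(overrides)] <- overrides
  structure(cfg, class = "pipeline_config")
}

method_conditions <- function(method, config) {
  switch(method,
    butterworth = stats::setNames(as.list(config$conditions$butterworth),
                                  paste0("band", config$conditions$butterworth)),
    cooccurrence = stats::setNames(as.list(config$conditions$cooccurrence),
                                   paste0("d", config$conditions$cooccurrence)),
    gmrf = stats::setNames(as.list(config$conditions$gmrf),
                           paste0("d", config$conditions$gmrf)),
    gabor = stats::setNames(as.list(config$conditions$gabor),
                            paste0("bins", config$conditions$gabor)),
    wavelet = list(wavelet = NA),
    stop("unknown method: ", method))
}

condition_params <- function(method, cond) {
  switch(method,
    butterworth = list(band = cond),
    cooccurrence = list(d = cond),
    gmrf = list(d = cond),
    gabor = list(n_bins = cond),
    wavelet = list())
}

#' Descriptor table for a set of images
#'
#' Computes one descriptor per image for a fixed method / colour space /
#' condition, returning the `n x p` matrix.
#'
#' @param images list of [rgb_image] objects.
#' @param method texture method id.
#' @param space colour space id.
#' @param params method parameters (see [descriptor_in_space()]).
#' @param verbose print progress.
#' @return Numeric matrix, one row per image.
#' @export
descriptor_table <- function(images, method, space, params = list(),
                             verbose = FALSE) {
  rows <- lapply(seq_along(images), function(i) {
    if (verbose && i %% 20L == 1L)
      message(sprintf("  descriptor %d/%d (%s/%s)", i, length(images),
                      method, space))
    descriptor_in_space(images[[i]], method, space, params)$values
  })
  do.call(rbind, rows)
}

#' Run one classification experiment on a dataset
#'
#' For the configured texture method, evaluates every condition x
#' classifier x colour space combination by stratified k-fold
#' cross-validation and then runs the statistical comparison per colour
#' space.
#'
#' @param method texture method id.
#' @param dataset a `synthetic_dataset` (or list with `images`, `labels`).
#' @param config a [pipeline_config()].
#' @param spaces colour spaces to evaluate.
#' @param verbose print stage progress.
#' @return List with `tables` (one `accuracy_table` per space),
#'   `comparisons` (one `comparison_report` per space) and the resolved
#'   `config`.
#' @export
run_experiment <- function(method, dataset, config = pipeline_config(),
                           spaces = c("gray", "lab", "opponent"),
                           verbose = FALSE) {
  conds <- method_conditions(method, config)
  tables <- list()
  comparisons <- list()
  for (space in spaces) {
    datasets <- lapply(conds, function(cond) {
      X <- descriptor_table(dataset$images, method, space,
                            condition_params(method, cond), verbose = verbose)
      labelled_dataset(X, dataset$labels)
    })
    tab <- accuracy_table(datasets, config$classifiers,
                          k = config$cv$k, seed = config$cv$seed,
                          colour_space = space)
    tables[[space]] <- tab
    comparisons[[space]] <- if (length(conds) >= 4L) {
      compare_classifiers(tab, alpha = config$stats$alpha)
    } else NULL   # too few conditions for the normality/ANOVA workflow
  }
  list(method = method, tables = tables, comparisons = comparisons,
       config = config)
}

## ---- fixture tables and the reproduction entry point ----

fixture_path <- function(name, fixtures_dir = NULL) {
  p <- if (is.null(fixtures_dir)) {
    system.file("extdata", name, package = "tearfilm")
  } else file.path(fixtures_dir, name)
  if (!nzchar(p) || !file.exists(p)) stop("missing fixture: ", name)
  p
}

#' Load a transcribed accuracy-table fixture
#'
#' The package ships the published per-condition accuracy tables of the
#' reference study as CSV fixtures (2-dp percentages), one file per
#' texture method, with rows per classifier x colour space and the printed
#' "Avg." column kept for cross-checking.
#'
#' @param method one of `"butterworth"`, `"wavelet"`, `"cooccurrence"`,
#'   `"markov"`, `"gabor"`.
#' @param space one of `"gray"`, `"lab"`, `"opponent"`.
#' @param fixtures_dir optional directory overriding the installed
#'   fixtures.
#' @return An `accuracy_table` with attribute `avg_printed` (the printed
#'   row means).
#' @export
load_accuracy_fixture <- function(method, space,
                                  fixtures_dir = NULL) {
  method <- match.arg(method, c("butterworth", "wavelet", "cooccurrence",
                                "markov", "gabor"))
  space <- match.arg(space, c("gray", "lab", "opponent"))
  df <- utils::read.csv(fixture_path(paste0("accuracy_", method, ".csv"),
                                     fixtures_dir))
  df <- df[df$space == space, ]
  vals <- as.matrix(df[, grep("^c[0-9]+$", names(df)), drop = FALSE])
  rownames(vals) <- df$classifier
  out <- as_accuracy_table(vals, colour_space = space)
  attr(out, "avg_printed") <- stats::setNames(df$avg_printed, df$classifier)
  out
}

#' Recompute the published statistical comparison from fixtures
#'
#' Re-runs the ANOVA (and Tukey where the ANOVA rejects) on every
#' method x colour-space block of the transcribed accuracy tables, using
#' the study's stated classifier exclusions, and compares the recomputed
#' degrees of freedom, F and sums of squares against the printed
#' reference values. A printed between-group SS known to be internally
#' inconsistent (it disagrees with its own MS x df and with
#' total - within) is flagged `ss_between_typo` in the reference fixture
#' and checked against the reconstructed value instead.
#'
#' @param fixtures_dir optional directory of fixture CSVs.
#' @param alpha significance level.
#' @param f_rtol relative tolerance on F and SS (default 0.005; the
#'   printed tables were computed on unrounded accuracies while the
#'   fixtures carry 2-dp roundings).
#' @return A data.frame report, one row per block, with recomputed and
#'   reference values, pass flags, and the Tukey best-set verdicts.
#' @export
reproduce_paper_stats <- function(fixtures_dir = NULL, alpha = 0.05,
                                  f_rtol = 0.005) {
  ref <- utils::read.csv(fixture_path("anova_reference.csv", fixtures_dir))
  best_ref <- utils::read.csv(fixture_path("best_classifiers_reference.csv",
                                           fixtures_dir))
  rows <- lapply(seq_len(nrow(ref)), function(i) {
    r <- ref[i, ]
    tab <- load_accuracy_fixture(r$method, r$space, fixtures_dir)
    excl <- if (nzchar(r$excluded %||% "") && !is.na(r$excluded))
      strsplit(r$excluded, ";")[[1]] else character(0)
    rep_ <- compare_classifiers(tab, alpha = alpha, excluded = excl)
    an <- rep_$anova
    ss_b_ref <- if (isTRUE(r$ss_between_typo))
      r$ms_between * r$df_between else r$ss_between
    br <- best_ref[best_ref$method == r$method & best_ref$space == r$space, ]
    best_expected <- if (isTRUE(br$no_significant_differences)) character(0)
      else strsplit(br$best_set, ";")[[1]]
    best_got <- if (rep_$no_significant_differences) character(0)
      else rep_$best_set
    data.frame(
      method = r$method, space = r$space,
      df_between = an$df_between, df_between_ref = r$df_between,
      df_within = an$df_within, df_within_ref = r$df_within,
      F = an$F, F_ref = r$F,
      ss_between = an$ss_between, ss_between_ref = ss_b_ref,
      ss_within = an$ss_within, ss_within_ref = r$ss_within,
      rejects = rep_$anova_rejects, rejects_ref = r$p_below_alpha,
      df_pass = (an$df_between == r$df_between &&
                 an$df_within == r$df_within),
      F_pass = abs(an$F - r$F) <= f_rtol * r$F,
      ss_pass = (abs(an$ss_between - ss_b_ref) <= f_rtol * ss_b_ref &&
                 abs(an$ss_within - r$ss_within) <= f_rtol * r$ss_within),
      best_set = paste(sort(best_got), collapse = ";"),
      best_set_ref = paste(sort(best_expected), collapse = ";"),
      best_set_pass = setequal(best_got, best_expected),
      stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
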