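#' Classifier-comparison statistics
#'
#' The accuracy rows of each classifier (one value per experimental
#' condition) are treated as samples. The workflow is: Lilliefors
#' normality gate per classifier, one-way ANOVA across the remaining
#' classifiers, and Tukey HSD pairwise comparison when the ANOVA rejects.
#'
#' @name stats-comparison
NULL

#' Lilliefors normality test
#'
#' Kolmogorov-Smirnov sup-distance between the sample ECDF and the normal
#' CDF with mean and standard deviation estimated from the sample. The
#' p-value is obtained by Monte-Carlo resampling from the fitted null
#' (seeded), which gives exact small-n behaviour without lookup tables.
#'
#' @param sample numeric vector, `n >= 4`, nonzero variance.
#' @param alpha significance level.
#' @param n_mc number of Monte-Carlo replicates.
#' @param seed integer seed for the resampling.
#' @return A `lilliefors_result` with `statistic`, `p_value`, `reject`.
#' @export
lilliefors_test <- function(sample, alpha = 0.05, n_mc = 10000L,
                            seed = 20120405L) {
  n <- length(sample)
  if (n < 4L) stop("need at least 4 observations")
  if (stats::sd(sample) == 0) stop("zero sample variance")
  stat_of <- function(x) {
    n <- length(x)
    xs <- sort(x)
    Fx <- stats::pnorm(xs, mean(x), stats::sd(x))
    max(abs(Fx - (seq_len(n) - 1L) / n), abs(Fx - seq_len(n) / n))
  }
  D <- stat_of(sample)
  set.seed(seed)
  null_D <- vapply(seq_len(n_mc), function(i) stat_of(stats::rnorm(n)),
                   numeric(1))
  p <- (1 + sum(null_D >= D)) / (n_mc + 1)
  structure(list(statistic = D, p_value = p, reject = (p < alpha),
                 alpha = alpha, n = n),
            class = "lilliefors_result")
}

#' One-way ANOVA
#'
#' Standard between/within decomposition of a set of independent groups;
#' the p-value comes from the F distribution with
#' `(df_between, df_within)` degrees of freedom.
#'
#' @param groups list of numeric vectors (>= 2 groups, each with >= 2
#'   values).
#' @return An `anova_result` with `ss_between`, `ss_within`, `ss_total`,
#'   `df_between`, `df_within`, `df_total`, `ms_between`, `ms_within`,
#'   `F`, `p_value`, and the group means.
#' @export
one_way_anova <- function(groups) {
  if (length(groups) < 2L) stop("need at least 2 groups")
  if (any(vapply(groups, length, 1L) < 2L))
    stop("every group needs at least 2 values")
  all_x <- unlist(groups)
  grand <- mean(all_x)
  n_i <- vapply(groups, length, 1L)
  m_i <- vapply(groups, mean, 1)
  ss_between <- sum(n_i * (m_i - grand)^2)
  ss_within <- sum(vapply(groups, function(g) sum((g - mean(g))^2), 1))
  df_between <- length(groups) - 1L
  df_within <- length(all_x) - length(groups)
  ms_within <- ss_within / df_within
  if (ms_within == 0) stop("zero within-group variance: F undefined")
  ms_between <- ss_between / df_between
  F_ <- ms_between / ms_within
  structure(list(ss_between = ss_between, ss_within = ss_within,
                 ss_total = ss_between + ss_within,
                 df_between = df_between, df_within = df_within,
                 df_total = df_between + df_within,
                 ms_between = ms_between, ms_within = ms_within,
                 F = F_,
                 p_value = stats::pf(F_, df_between, df_within,
                                     lower.tail = FALSE),
                 group_means = m_i, group_sizes = n_i),
            class = "anova_result")
}

#' @export
print.anova_result <- function(x, ...) {
  cat(sprintf("Between  SS %.2f  df %d  MS %.2f  F %.2f  p %.3g\n",
              x$ss_between, x$df_between, x$ms_between, x$F, x$p_value))
  cat(sprintf("Within   SS %.2f  df %d  MS %.2f\n",
              x$ss_within, x$df_within, x$ms_within))
  cat(sprintf("Total    SS %.2f  df %d\n", x$ss_total, x$df_total))
  invisible(x)
}

#' Tukey HSD multiple comparison
#'
#' All-pairs comparison of group means using the studentized range
#' distribution with the ANOVA within-group mean square (equal group
#' sizes). `best_set` lists the groups not significantly below the top
#' performer.
#'
#' @param groups named list of numeric vectors (equal sizes).
#' @param alpha family-wise significance level.
#' @return A `tukey_result` with the pairwise `difference` and
#'   `significant` matrices, `p_values`, and `best_set`.
#' @export
tukey_hsd <- function(groups, alpha = 0.05) {
  an <- one_way_anova(groups)
  n_i <- an$group_sizes
  if (length(unique(n_i)) != 1L)
    stop("tukey_hsd requires equal group sizes")
  n <- n_i[1]
  k <- length(groups)
  nm <- names(groups) %||% paste0("g", seq_len(k))
  m <- an$group_means
  se <- sqrt(an$ms_within / n)
  diff_m <- outer(m, m, `-`)
  q_obs <- abs(diff_m) / se
  p <- matrix(stats::ptukey(q_obs, k, an$df_within, lower.tail = FALSE), k, k)
  diag(p) <- 1
  sig <- p < alpha
  dimnames(diff_m) <- dimnames(p) <- dimnames(sig) <- list(nm, nm)
  top <- which.max(m)
  best_set <- nm[!sig[top, ] | seq_len(k) == top]
  structure(list(difference = diff_m, p_values = p, significant = sig,
                 best_set = best_set, alpha = alpha, anova = an),
            class = "tukey_result")
}

#' Full classifier-comparison workflow on an accuracy table
#'
#' (1) Lilliefors test per classifier row; rows failing normality at
#' `alpha` are excluded — unless `excluded` is supplied, in which case that
#' list is honoured verbatim (this pins the exclusion decisions
#' deterministically, independent of the Lilliefors Monte-Carlo detail).
#' (2) One-way ANOVA across the remaining rows, treating each condition
#' column as an observation. (3) Tukey HSD only if the ANOVA rejects.
#' Every decision is recorded in the returned report.
#'
#' @param table an `accuracy_table` (see [as_accuracy_table()]) or plain
#'   classifiers x conditions matrix; the `Avg.` column is dropped.
#' @param alpha significance level used throughout.
#' @param excluded optional character vector of classifier rows to exclude
#'   before the ANOVA (overrides the Lilliefors gate).
#' @param lilliefors_seed seed for the Monte-Carlo p-values.
#' @return A `comparison_report` with elements `lilliefors` (per-row
#'   results), `excluded`, `anova`, `anova_rejects`, `tukey` (or `NULL`),
#'   `best_set`, `alpha`.
#' @export
compare_classifiers <- function(table, alpha = 0.05, excluded = NULL,
                                lilliefors_seed = 20120405L) {
  vals <- if (inherits(table, "accuracy_table")) accuracy_values(table)
          else as.matrix(table)
  if (is.null(rownames(vals))) rownames(vals) <- paste0("clf", seq_len(nrow(vals)))
  lf <- lapply(seq_len(nrow(vals)), function(i)
    lilliefors_test(vals[i, ], alpha = alpha, seed = lilliefors_seed + i))
  names(lf) <- rownames(vals)
  if (is.null(excluded)) {
    excluded <- rownames(vals)[vapply(lf, `[[`, TRUE, "reject")]
  } else {
    bad <- setdiff(excluded, rownames(vals))
    if (length(bad)) stop("unknown classifiers in `excluded`: ",
                          paste(bad, collapse = ", "))
  }
  keep <- setdiff(rownames(vals), excluded)
  if (length(keep) < 2L) stop("fewer than 2 classifier rows remain")
  groups <- stats::setNames(
    lapply(keep, function(r) vals[r, ]), keep)
  an <- one_way_anova(groups)
  rejects <- an$p_value < alpha
  tk <- if (rejects) tukey_hsd(groups, alpha) else NULL
  best <- if (rejects) tk$best_set else keep
  structure(list(lilliefors = lf, excluded = excluded, anova = an,
                 anova_rejects = rejects, tukey = tk, best_set = best,
                 alpha = alpha,
                 no_significant_differences = !rejects),
            class = "comparison_report")
}

#' @export
print.comparison_report <- function(x, ...) {
  cat("Excluded (normality):",
      if (length(x$excluded)) paste(x$excluded, collapse = ", ") else "none",
      "\n")
  print(x$anova)
  if (x$anova_rejects) {
    cat("Tukey best set:", paste(x$best_set, collapse = ", "), "\n")
  } else {
    cat("ANOVA accepted the null: no significant differences\n")
  }
  invisible(x)
}
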