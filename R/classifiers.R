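#' Classifier families
#'
#' Five classifier families are evaluated on the descriptor tables:
#' Gaussian naive Bayes (NB), a logistic model tree (LMT: a shallow CART
#' tree with multinomial logistic models at the leaves — a tractable
#' approximation of full LMT induction), a random tree (RT: one unpruned
#' tree with a random feature subset at each node), a random forest (RF:
#' bagged random trees with majority vote), and an RBF-kernel support
#' vector machine (SVM, one-vs-one for the four classes, trained with an
#' in-package SMO solver). All are implemented in-package since no
#' classifier library is assumed at run time.
#'
#' `make_classifier()` returns an object with `fit(X, y)` and
#' `predict(model, X)` semantics via the S3 generics [fit_classifier()]
#' and `predict()`.
#'
#' @param id one of `"NB"`, `"LMT"`, `"RT"`, `"RF"`, `"SVM"`
#'   (case-insensitive).
#' @param hyperparams named list of overrides; see Details.
#'
#' @details Hyperparameter defaults: RT/RF `mtry = floor(sqrt(p))`,
#'   RF `n_trees = 100`, `sample_replace = TRUE`; LMT `max_depth = 3`,
#'   `min_leaf = 10`, ridge `lambda = 1e-2`; SVM `C = 10`, `gamma = 1/p`,
#'   or an inner 5-fold grid search over `C in 10^(-1..3)`,
#'   `gamma in 10^(-4..1)` when `tune = TRUE`. NB uses a small variance
#'   floor. All stated in the resolved config of every run.
#' @return A `tf_classifier` specification.
#' @export
make_classifier <- function(id, hyperparams = list()) {
  id <- toupper(id)
  if (!id %in% c("NB", "LMT", "RT", "RF", "SVM"))
    stop("unknown classifier id: ", id)
  defaults <- switch(id,
    NB = list(var_floor = 1e-9),
    LMT = list(max_depth = 3L, min_leaf = 10L, lambda = 1e-2),
    RT = list(mtry = NULL, min_split = 2L, max_depth = 25L),
    RF = list(n_trees = 100L, mtry = NULL, min_split = 2L, max_depth = 25L,
              sample_replace = TRUE, sample_fraction = 1),
    SVM = list(C = 10, gamma = NULL, tune = FALSE,
               C_grid = 10^(-1:3), gamma_grid = 10^(-4:1), tune_folds = 5L)
  )
  unknown <- setdiff(names(hyperparams), names(defaults))
  if (length(unknown)) stop("invalid hyperparameters: ",
                            paste(unknown, collapse = ", "))
  defaults[names(hyperparams)] <- hyperparams
  structure(list(id = id, hyperparams = defaults), class = "tf_classifier")
}

#' Fit a classifier specification to data
#'
#' @param clf a [make_classifier()] specification.
#' @param X numeric `n x p` matrix of descriptors.
#' @param y factor (or coercible) of class labels.
#' @param seed optional integer seed for the stochastic learners (RT, RF,
#'   SVM working-set selection).
#' @return A fitted model answering to `predict(model, Xnew)` with a factor
#'   of predicted labels.
#' @export
fit_classifier <- function(clf, X, y, seed = NULL) {
  stopifnot(inherits(clf, "tf_classifier"))
  X <- as.matrix(X)
  if (anyNA(X) || any(!is.finite(X))) stop("non-finite descriptor entries")
  y <- factor(y)
  if (!is.null(seed)) set.seed(seed)
  hp <- clf$hyperparams
  model <- switch(clf$id,
    NB = nb_fit(X, y, hp$var_floor),
    LMT = lmt_fit(X, y, hp$max_depth, hp$min_leaf, hp$lambda),
    RT = rtree_fit(X, y, mtry = hp$mtry %||% max(1L, floor(sqrt(ncol(X)))),
                   min_split = hp$min_split, max_depth = hp$max_depth,
                   bootstrap = FALSE),
    RF = rf_fit(X, y, hp),
    SVM = svm_fit(X, y, hp)
  )
  model$classes <- levels(y)
  model$id <- clf$id
  class(model) <- c(paste0("tf_", tolower(clf$id)), "tf_model")
  model
}

## ---- Gaussian naive Bayes ----

nb_fit <- function(X, y, var_floor = 1e-9) {
  cls <- levels(y)
  mu <- t(vapply(cls, function(k) colMeans(X[y == k, , drop = FALSE]),
                 numeric(ncol(X))))
  v <- t(vapply(cls, function(k) {
    vv <- apply(X[y == k, , drop = FALSE], 2L, stats::var)
    vv[!is.finite(vv)] <- 0
    pmax(vv, var_floor)
  }, numeric(ncol(X))))
  prior <- as.numeric(table(y)[cls]) / length(y)
  list(mu = mu, var = v, prior = prior)
}

#' @export
predict.tf_nb <- function(object, newdata, ...) {
  X <- as.matrix(newdata)
  ll <- vapply(seq_along(object$classes), function(k) {
    mu <- object$mu[k, ]; v <- object$var[k, ]
    rowSums(-0.5 * (sweep(X, 2L, mu)^2) / rep(v, each = nrow(X)) -
            0.5 * rep(log(2 * pi * v), each = nrow(X))) +
      log(object$prior[k])
  }, numeric(nrow(X)))
  factor(object$classes[max.col(ll, ties.method = "first")],
         levels = object$classes)
}

## ---- CART-style trees with optional random feature subsets ----

gini_impurity <- function(counts) {
  n <- sum(counts)
  if (n == 0) return(0)
  1 - sum((counts / n)^2)
}

# Recursive builder; node: list(leaf, class) or list(leaf=FALSE, var, cut, L, R)
build_tree <- function(X, y, mtry, min_split, max_depth, depth = 0L) {
  n <- length(y)
  tab <- tabulate(y, nbins = nlevels(y))
  if (n < min_split || depth >= max_depth || sum(tab > 0) == 1L) {
    return(list(leaf = TRUE, class = which.max(tab)))
  }
  p <- ncol(X)
  vars <- if (mtry >= p) seq_len(p) else sample.int(p, mtry)
  best <- NULL
  parent_imp <- gini_impurity(tab)
  for (v in vars) {
    xv <- X[, v]
    ord <- order(xv)
    xs <- xv[ord]; ys <- as.integer(y[ord])
    cum <- apply(stats::model.matrix(~ 0 + factor(ys, levels = seq_len(nlevels(y)))),
                 2L, cumsum)
    # candidate cuts between distinct consecutive values
    distinct <- which(xs[-n] < xs[-1L])
    if (!length(distinct)) next
    for (i in distinct) {
      lc <- cum[i, ]; rc <- tab - lc
      imp <- (i * gini_impurity(lc) + (n - i) * gini_impurity(rc)) / n
      if (is.null(best) || imp < best$imp - 1e-12) {
        best <- list(imp = imp, var = v, cut = (xs[i] + xs[i + 1L]) / 2)
      }
    }
  }
  if (is.null(best) || best$imp >= parent_imp - 1e-12) {
    return(list(leaf = TRUE, class = which.max(tab)))
  }
  left <- X[, best$var] <= best$cut
  list(leaf = FALSE, var = best$var, cut = best$cut,
       L = build_tree(X[left, , drop = FALSE], y[left], mtry, min_split,
                      max_depth, depth + 1L),
       R = build_tree(X[!left, , drop = FALSE], y[!left], mtry, min_split,
                      max_depth, depth + 1L))
}

tree_predict_idx <- function(node, X) {
  out <- integer(nrow(X))
  rec <- function(node, idx) {
    if (!length(idx)) return()
    if (node$leaf) { out[idx] <<- node$class; return() }
    left <- X[idx, node$var] <= node$cut
    rec(node$L, idx[left]); rec(node$R, idx[!left])
  }
  rec(node, seq_len(nrow(X)))
  out
}

rtree_fit <- function(X, y, mtry, min_split = 2L, max_depth = 25L,
                      bootstrap = FALSE, sample_fraction = 1) {
  idx <- if (bootstrap) {
    sample.int(nrow(X), size = max(1L, round(sample_fraction * nrow(X))),
               replace = TRUE)
  } else seq_len(nrow(X))
  list(tree = build_tree(X[idx, , drop = FALSE], y[idx], mtry, min_split,
                         max_depth))
}

#' @export
predict.tf_rt <- function(object, newdata, ...) {
  X <- as.matrix(newdata)
  factor(object$classes[tree_predict_idx(object$tree, X)],
         levels = object$classes)
}

rf_fit <- function(X, y, hp) {
  mtry <- hp$mtry %||% max(1L, floor(sqrt(ncol(X))))
  trees <- lapply(seq_len(hp$n_trees), function(b) {
    rtree_fit(X, y, mtry, hp$min_split, hp$max_depth,
              bootstrap = hp$sample_replace,
              sample_fraction = hp$sample_fraction)$tree
  })
  list(trees = trees)
}

#' @export
predict.tf_rf <- function(object, newdata, ...) {
  X <- as.matrix(newdata)
  votes <- matrix(0L, nrow(X), length(object$classes))
  for (tr in object$trees) {
    idx <- tree_predict_idx(tr, X)
    votes[cbind(seq_len(nrow(X)), idx)] <-
      votes[cbind(seq_len(nrow(X)), idx)] + 1L
  }
  factor(object$classes[max.col(votes, ties.method = "first")],
         levels = object$classes)
}

## ---- multinomial logistic regression (softmax, ridge) ----

softmax_fit <- function(X, y, lambda = 1e-2, maxit = 200L) {
  K <- nlevels(y); p <- ncol(X)
  if (K == 1L) return(list(W = NULL, single = levels(y)))
  Xa <- cbind(1, X)
  Y <- stats::model.matrix(~ 0 + y)
  negll <- function(w) {
    W <- matrix(w, p + 1L, K - 1L)
    eta <- cbind(Xa %*% W, 0)
    eta <- eta - apply(eta, 1L, max)
    logz <- log(rowSums(exp(eta)))
    -sum(rowSums(Y * eta) - logz) + lambda * sum(w^2) / 2
  }
  grad <- function(w) {
    W <- matrix(w, p + 1L, K - 1L)
    eta <- cbind(Xa %*% W, 0)
    eta <- eta - apply(eta, 1L, max)
    Pm <- exp(eta) / rowSums(exp(eta))
    G <- t(Xa) %*% (Pm[, -K, drop = FALSE] - Y[, -K, drop = FALSE])
    as.numeric(G) + lambda * w
  }
  w0 <- numeric((p + 1L) * (K - 1L))
  opt <- stats::optim(w0, negll, grad, method = "BFGS",
                      control = list(maxit = maxit))
  list(W = matrix(opt$par, p + 1L, K - 1L), single = NULL)
}

softmax_predict <- function(model, X, classes) {
  if (!is.null(model$single)) return(rep(model$single, nrow(X)))
  eta <- cbind(cbind(1, X) %*% model$W, 0)
  classes[max.col(eta, ties.method = "first")]
}

## ---- logistic model tree (shallow CART + softmax leaves) ----

lmt_fit <- function(X, y, max_depth = 3L, min_leaf = 10L, lambda = 1e-2) {
  tree <- build_tree(X, y, mtry = ncol(X), min_split = 2L * min_leaf,
                     max_depth = max_depth)
  # attach a softmax model at each leaf reached by >= min_leaf samples and
  # more than one class; otherwise the leaf keeps its majority class
  leaf_paths <- list()
  assign_models <- function(node, idx) {
    if (node$leaf) {
      ys <- droplevels(y[idx])
      if (length(idx) >= min_leaf && nlevels(ys) > 1L) {
        node$model <- softmax_fit(X[idx, , drop = FALSE], ys, lambda)
        node$model_classes <- levels(ys)
      }
      return(node)
    }
    left <- X[idx, node$var] <= node$cut
    node$L <- assign_models(node$L, idx[left])
    node$R <- assign_models(node$R, idx[!left])
    node
  }
  list(tree = assign_models(tree, seq_len(nrow(X))))
}

#' @export
predict.tf_lmt <- function(object, newdata, ...) {
  X <- as.matrix(newdata)
  out <- character(nrow(X))
  classes <- object$classes
  rec <- function(node, idx) {
    if (!length(idx)) return()
    if (node$leaf) {
      if (!is.null(node$model)) {
        out[idx] <<- softmax_predict(node$model, X[idx, , drop = FALSE],
                                     node$model_classes)
      } else {
        out[idx] <<- classes[node$class]
      }
      return()
    }
    left <- X[idx, node$var] <= node$cut
    rec(node$L, idx[left]); rec(node$R, idx[!left])
  }
  rec(object$tree, seq_len(nrow(X)))
  factor(out, levels = classes)
}

## ---- RBF SVM (one-vs-one, SMO) ----

svm_fit <- function(X, y, hp) {
  gamma <- hp$gamma %||% (1 / ncol(X))
  C <- hp$C
  if (isTRUE(hp$tune)) {
    best <- svm_grid_search(X, y, hp$C_grid, hp$gamma_grid, hp$tune_folds)
    C <- best$C; gamma <- best$gamma
  }
  cls <- levels(y)
  pairs <- utils::combn(seq_along(cls), 2L)
  models <- lapply(seq_len(ncol(pairs)), function(q) {
    k1 <- pairs[1, q]; k2 <- pairs[2, q]
    sel <- y %in% cls[c(k1, k2)]
    Xs <- X[sel, , drop = FALSE]
    ys <- ifelse(y[sel] == cls[k1], 1, -1)
    fit <- smo_train(Xs, ys, C, gamma)
    list(k1 = k1, k2 = k2, X = Xs, y = ys,
         alpha = fit$alpha, b = fit$b)
  })
  list(models = models, gamma = gamma, C = C)
}

svm_grid_search <- function(X, y, C_grid, gamma_grid, folds = 5L) {
  fold_id <- stratified_fold_ids(y, min(folds, min(table(y))))
  best <- list(acc = -1, C = C_grid[1], gamma = gamma_grid[1])
  for (C in C_grid) for (g in gamma_grid) {
    correct <- 0L
    for (f in sort(unique(fold_id))) {
      tr <- fold_id != f
      m <- svm_fit(X[tr, , drop = FALSE], droplevels(y[tr]),
                   list(C = C, gamma = g, tune = FALSE))
      m$classes <- levels(droplevels(y[tr]))
      class(m) <- c("tf_svm", "tf_model")
      pred <- predict(m, X[!tr, , drop = FALSE])
      correct <- correct + sum(as.character(pred) == as.character(y[!tr]))
    }
    if (correct > best$acc) best <- list(acc = correct, C = C, gamma = g)
  }
  best
}

#' @export
predict.tf_svm <- function(object, newdata, ...) {
  X <- as.matrix(newdata)
  votes <- matrix(0L, nrow(X), length(object$classes))
  for (m in object$models) {
    dec <- smo_decision(m$X, m$y, m$alpha, m$b, object$gamma, X)
    win <- ifelse(dec >= 0, m$k1, m$k2)
    votes[cbind(seq_len(nrow(X)), win)] <-
      votes[cbind(seq_len(nrow(X)), win)] + 1L
  }
  factor(object$classes[max.col(votes, ties.method = "first")],
         levels = object$classes)
}
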