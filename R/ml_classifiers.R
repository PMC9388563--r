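# The four classifier families of the response-prediction harness.
# Extremely randomised trees, gradient boosting and AdaBoost share the
# compiled CART learner in src/trees.cpp; the multi-layer perceptron is a
# small tanh network trained by BFGS with analytic gradients. No suitable
# tree-ensemble or neural package ships in the target image, so these are
# implemented here behind a uniform fit/predict/importance surface.

#' Classifier families of the response harness
#' @return Character vector of the four family names.
#' @export
classifier_families <- function() {
  c("extra_trees", "gradient_boosting", "adaboost", "mlp")
}

#' Default hyper-parameters per family
#'
#' Mirrors the common published defaults: 100 unpruned extra-trees with
#' sqrt(p) features per split; 100 depth-3 gradient-boosted trees at
#' learning rate 0.1; 50 AdaBoost stumps; one 16-unit hidden layer for the
#' perceptron.
#'
#' @param family one of [classifier_families()].
#' @return Named list of parameters.
#' @export
default_params <- function(family) {
  switch(match.arg(family, classifier_families()),
    extra_trees = list(n_trees = 100L, max_depth = 0L, min_leaf = 1L),
    gradient_boosting = list(n_trees = 100L, max_depth = 3L,
                             learning_rate = 0.1, min_leaf = 1L),
    adaboost = list(n_trees = 50L, max_depth = 1L, learning_rate = 1),
    mlp = list(hidden = 16L, alpha = 1e-4, maxit = 200L))
}

#' Default hyper-parameter grids per family
#'
#' Small published-style grids (the harness, not the grid, is the method):
#' tree counts 100/200/500, depths 2/3/5, learning rates 0.01/0.1,
#' perceptron hidden layouts (8), (16), (16, 8).
#'
#' @inheritParams default_params
#' @return List of parameter lists, one per grid point.
#' @export
default_grid <- function(family) {
  family <- match.arg(family, classifier_families())
  expand_grid_list <- function(...) {
    g <- expand.grid(..., stringsAsFactors = FALSE)
    lapply(seq_len(nrow(g)), function(i) as.list(g[i, , drop = FALSE]))
  }
  switch(family,
    extra_trees = expand_grid_list(n_trees = c(100L, 200L, 500L),
                                   max_depth = c(2L, 3L, 5L)),
    gradient_boosting = expand_grid_list(n_trees = c(100L, 200L, 500L),
                                         max_depth = c(2L, 3L, 5L),
                                         learning_rate = c(0.01, 0.1)),
    adaboost = expand_grid_list(n_trees = c(100L, 200L, 500L),
                                learning_rate = c(0.01, 0.1)),
    mlp = lapply(list(8L, 16L, c(16L, 8L)),
                 function(h) list(hidden = h, alpha = 1e-4,
                                  maxit = 200L)))
}

#' Fit one classifier
#'
#' @param family one of [classifier_families()].
#' @param X numeric feature matrix (no missing values).
#' @param y binary labels (0/1).
#' @param params named parameter list; missing entries filled from
#'   [default_params()].
#' @param seed integer seed for the family's internal randomness.
#' @return A fitted model object (class `tiic_<family>`) usable with
#'   [predict_prob()] and [feature_importance()].
#' @export
fit_classifier <- function(family, X, y, params = list(), seed = 1L) {
  family <- match.arg(family, classifier_families())
  X <- as.matrix(X); storage.mode(X) <- "double"
  y <- as.numeric(y)
  stopifnot(all(y %in% c(0, 1)), !anyNA(X))
  if (length(unique(y)) < 2)
    stop("labels are single-class; cannot fit", call. = FALSE)
  p <- modifyList(default_params(family), params)
  seed <- as.integer(seed %% .Machine$integer.max)
  model <- switch(family,
    extra_trees = {
      mtry <- max(1L, as.integer(ceiling(sqrt(ncol(X)))))
      m <- .cpp_extra_trees(X, y, p$n_trees, p$max_depth, p$min_leaf,
                            mtry, seed)
      structure(m, class = "tiic_extra_trees")
    },
    gradient_boosting = {
      m <- .cpp_gbm(X, y, p$n_trees, p$max_depth, p$learning_rate,
                    p$min_leaf, seed)
      structure(m, class = "tiic_gbm")
    },
    adaboost = {
      m <- .cpp_adaboost(X, y, p$n_trees, p$max_depth, p$learning_rate,
                         1L, seed)
      structure(m, class = "tiic_adaboost")
    },
    mlp = .mlp_fit(X, y, hidden = p$hidden, alpha = p$alpha,
                   maxit = p$maxit, seed = seed))
  attr(model, "params") <- p
  attr(model, "features") <- colnames(X)
  model
}

#' Predicted probability of the positive class
#' @param model a fitted model from [fit_classifier()].
#' @param X feature matrix.
#' @return Numeric vector of scores in \[0, 1\].
#' @export
predict_prob <- function(model, X) UseMethod("predict_prob")

#' @export
predict_prob.tiic_extra_trees <- function(model, X) {
  .cpp_forest_predict(model$trees, .as_dbl(X))
}
#' @export
predict_prob.tiic_gbm <- function(model, X) {
  .cpp_gbm_predict(model, .as_dbl(X))
}
#' @export
predict_prob.tiic_adaboost <- function(model, X) {
  .cpp_adaboost_predict(model, .as_dbl(X))
}

.as_dbl <- function(X) {
  X <- as.matrix(X); storage.mode(X) <- "double"; X
}

#' Per-feature importance of a fitted classifier
#'
#' Tree families expose normalised impurity-decrease importances
#' (summing to 1). The perceptron has no impurity notion; it uses
#' permutation importance (mean AUC drop over `n_perm` shuffles of each
#' column, clipped at 0 and normalised) — an extension, since the
#' published models only report tree importances.
#'
#' @param model fitted model.
#' @param X,y data for permutation importance (required for `mlp`).
#' @param n_perm permutations per feature for `mlp`.
#' @param seed permutation seed.
#' @return Named numeric vector of non-negative weights.
#' @export
feature_importance <- function(model, X = NULL, y = NULL, n_perm = 20L,
                               seed = 1L) UseMethod("feature_importance")

.named_imp <- function(v, model) {
  nm <- attr(model, "features")
  if (!is.null(nm)) names(v) <- nm
  v
}

#' @export
feature_importance.tiic_extra_trees <- function(model, X = NULL, y = NULL,
                                                n_perm = 20L, seed = 1L) {
  .named_imp(model$importance, model)
}
#' @export
feature_importance.tiic_gbm <- feature_importance.tiic_extra_trees
#' @export
feature_importance.tiic_adaboost <- feature_importance.tiic_extra_trees

#' @export
feature_importance.tiic_mlp <- function(model, X = NULL, y = NULL,
                                        n_perm = 20L, seed = 1L) {
  if (is.null(X) || is.null(y))
    stop("permutation importance for the perceptron needs X and y",
         call. = FALSE)
  X <- .as_dbl(X)
  base_auc <- auc_score(predict_prob(model, X), y)
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(seed)
  drops <- vapply(seq_len(ncol(X)), function(j) {
    mean(vapply(seq_len(n_perm), function(k) {
      Xp <- X
      Xp[, j] <- Xp[sample(nrow(Xp)), j]
      base_auc - auc_score(predict_prob(model, Xp), y)
    }, 0))
  }, 0)
  drops <- pmax(drops, 0)
  v <- if (sum(drops) > 0) drops / sum(drops) else
    rep(1 / ncol(X), ncol(X))
  .named_imp(v, model)
}

#' Area under the ROC curve
#'
#' Rank-based (Mann-Whitney) AUC with ties handled by mid-ranks, so
#' `auc_score(s, y) + auc_score(s, 1 - y) == 1`.
#'
#' @param scores numeric scores.
#' @param labels binary labels (0/1).
#' @return AUC in \[0, 1\].
#' @export
auc_score <- function(scores, labels) {
  labels <- as.numeric(labels)
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0)
    stop("AUC requires both classes", call. = FALSE)
  r <- rank(scores)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# --- multi-layer perceptron ------------------------------------------------

.save_rng <- function() {
  if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
}
.restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

# parameters flattened as (W1, b1, ..., Wout, bout); tanh hidden units,
# logistic output, cross-entropy loss with L2 penalty alpha/(2n)*||W||^2
.mlp_shapes <- function(p, hidden) {
  sizes <- c(p, hidden, 1L)
  lapply(seq_len(length(sizes) - 1L),
         function(l) c(sizes[l], sizes[l + 1L]))
}

.mlp_unpack <- function(par, shapes) {
  out <- vector("list", length(shapes))
  off <- 0L
  for (l in seq_along(shapes)) {
    nw <- shapes[[l]][1] * shapes[[l]][2]
    W <- matrix(par[off + seq_len(nw)], shapes[[l]][1], shapes[[l]][2])
    off <- off + nw
    b <- par[off + seq_len(shapes[[l]][2])]
    off <- off + shapes[[l]][2]
    out[[l]] <- list(W = W, b = b)
  }
  out
}

.mlp_forward <- function(layers, X) {
  a <- X
  acts <- list(a)
  L <- length(layers)
  for (l in seq_len(L - 1L)) {
    a <- tanh(sweep(a %*% layers[[l]]$W, 2, layers[[l]]$b, "+"))
    acts[[l + 1L]] <- a
  }
  z <- sweep(a %*% layers[[L]]$W, 2, layers[[L]]$b, "+")
  list(acts = acts, prob = 1 / (1 + exp(-z)))
}

.mlp_fit <- function(X, y, hidden = 16L, alpha = 1e-4, maxit = 200L,
                     seed = 1L) {
  hidden <- as.integer(unlist(hidden))
  n <- nrow(X); p <- ncol(X)
  ctr <- colMeans(X)
  scl <- apply(X, 2, sd); scl[scl == 0] <- 1
  Xs <- sweep(sweep(X, 2, ctr), 2, scl, "/")
  shapes <- .mlp_shapes(p, hidden)
  npar <- sum(vapply(shapes, function(s) s[1] * s[2] + s[2], 0))
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(seed)
  par0 <- unlist(lapply(shapes, function(s) {
    lim <- sqrt(6 / (s[1] + s[2]))
    c(runif(s[1] * s[2], -lim, lim), rep(0, s[2]))
  }))
  stopifnot(length(par0) == npar)

  loss_grad <- function(par, want_grad) {
    layers <- .mlp_unpack(par, shapes)
    fw <- .mlp_forward(layers, Xs)
    pr <- pmin(pmax(fw$prob[, 1], 1e-12), 1 - 1e-12)
    pen <- sum(vapply(layers, function(l) sum(l$W^2), 0))
    loss <- -mean(y * log(pr) + (1 - y) * log(1 - pr)) +
      0.5 * alpha * pen / n
    if (!want_grad) return(loss)
    L <- length(layers)
    grads <- vector("list", L)
    delta <- matrix((fw$prob[, 1] - y) / n, n, 1)
    for (l in L:1) {
      a_prev <- fw$acts[[l]]
      gW <- crossprod(a_prev, delta) + (alpha / n) * layers[[l]]$W
      gb <- colSums(delta)
      grads[[l]] <- c(as.numeric(gW), gb)
      if (l > 1L)
        delta <- (delta %*% t(layers[[l]]$W)) * (1 - fw$acts[[l]]^2)
    }
    attr(loss, "gradient") <- unlist(grads)
    loss
  }
  fn <- function(par) loss_grad(par, FALSE)
  gr <- function(par) attr(loss_grad(par, TRUE), "gradient")
  opt <- optim(par0, fn, gr, method = "BFGS",
               control = list(maxit = maxit, reltol = 1e-9))
  structure(list(par = opt$par, shapes = shapes, hidden = hidden,
                 center = ctr, scale = scl, value = opt$value,
                 convergence = opt$convergence),
            class = "tiic_mlp")
}

#' @export
predict_prob.tiic_mlp <- function(model, X) {
  X <- .as_dbl(X)
  Xs <- sweep(sweep(X, 2, model$center), 2, model$scale, "/")
  layers <- .mlp_unpack(model$par, model$shapes)
  as.numeric(.mlp_forward(layers, Xs)$prob)
}
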