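# Responder-prediction harness: univariate logistic feature screening,
# then repeated stratified 3-fold cross-validation with optional inner
# grid search for each classifier family. Each repetition reshuffles the
# folds with a repetition-specific seed derived from one master seed; the
# report carries the full AUC distribution, its mean and 2.5/97.5
# percentile interval, the modal chosen parameters and averaged feature
# importances.

#' Univariate logistic screening of features against response
#'
#' One logistic regression per feature: odds ratio, Wald 95% CI and
#' p-value, with the direction of association. Complete separation is
#' detected and re-fitted with a weak ridge penalty (labelled, p set to
#' `NA`); zero-variance features are flagged degenerate with an undefined
#' OR.
#'
#' @param X feature matrix or data.frame.
#' @param y binary responder labels (needs >= 2 of each class).
#' @return data.frame: `feature`, `or`, `ci_lo`, `ci_hi`, `p`,
#'   `direction` (`"positive"`/`"negative"`), `method`
#'   (`"mle"`/`"penalised"`/`"degenerate"`).
#' @export
screen_features <- function(X, y) {
  X <- as.data.frame(X)
  y <- as.numeric(y)
  if (sum(y == 1) < 2 || sum(y == 0) < 2)
    stop("need >= 2 responders and >= 2 non-responders", call. = FALSE)
  out <- lapply(names(X), function(f) {
    x <- X[[f]]
    if (var(x, na.rm = TRUE) == 0)
      return(data.frame(feature = f, or = NA_real_, ci_lo = NA_real_,
                        ci_hi = NA_real_, p = NA_real_,
                        direction = NA_character_, method = "degenerate",
                        stringsAsFactors = FALSE))
    sep <- FALSE
    fit <- withCallingHandlers(
      glm(y ~ x, family = binomial()),
      warning = function(w) {
        if (grepl("fitted probabilities|did not converge",
                  conditionMessage(w))) sep <<- TRUE
        invokeRestart("muffleWarning")
      })
    b <- coef(fit)[2]
    if (sep || !is.finite(b) || abs(b) > 15) {
      b <- .ridge_logistic(x, y, lambda = 0.5)
      return(data.frame(feature = f, or = exp(b), ci_lo = NA_real_,
                        ci_hi = NA_real_, p = NA_real_,
                        direction = if (b >= 0) "positive" else "negative",
                        method = "penalised", stringsAsFactors = FALSE))
    }
    s <- summary(fit)$coefficients
    se <- s[2, "Std. Error"]
    data.frame(feature = f, or = exp(b),
               ci_lo = exp(b - qnorm(0.975) * se),
               ci_hi = exp(b + qnorm(0.975) * se),
               p = s[2, "Pr(>|z|)"],
               direction = if (b >= 0) "positive" else "negative",
               method = "mle", stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

# ridge-penalised univariate logistic slope via IRLS; finite under
# complete separation
.ridge_logistic <- function(x, y, lambda = 0.5, maxit = 100L) {
  xs <- (x - mean(x)) / ifelse(sd(x) > 0, sd(x), 1)
  beta <- c(0, 0) # intercept, slope
  for (it in seq_len(maxit)) {
    eta <- beta[1] + beta[2] * xs
    p <- 1 / (1 + exp(-eta))
    w <- pmax(p * (1 - p), 1e-8)
    z <- eta + (y - p) / w
    XtWX <- rbind(c(sum(w), sum(w * xs)),
                  c(sum(w * xs), sum(w * xs^2) + lambda))
    XtWz <- c(sum(w * z), sum(w * xs * z) )
    new <- solve(XtWX, XtWz)
    if (max(abs(new - beta)) < 1e-10) { beta <- new; break }
    beta <- new
  }
  beta[2] / ifelse(sd(x) > 0, sd(x), 1) # back to the original scale
}

# stratified k folds: permute within class, deal round-robin
.stratified_folds <- function(y, k) {
  fold <- integer(length(y))
  for (cls in unique(y)) {
    idx <- which(y == cls)
    if (length(idx) < k)
      stop("class ", cls, " has fewer members (", length(idx),
           ") than folds (", k, "); stratified folding impossible",
           call. = FALSE)
    fold[idx] <- (sample(length(idx)) %% k) + 1L
  }
  fold
}

# inner grid selection: mean AUC over an inner stratified CV on the
# training fold
.select_params <- function(X, y, family, grid, inner_folds, seed) {
  if (is.null(grid) || length(grid) == 0) return(default_params(family))
  fold <- .stratified_folds(y, inner_folds)
  mean_auc <- vapply(seq_along(grid), function(gi) {
    aucs <- vapply(seq_len(inner_folds), function(f) {
      tr <- fold != f; te <- !tr
      if (length(unique(y[te])) < 2) return(NA_real_)
      m <- fit_classifier(family, X[tr, , drop = FALSE], y[tr],
                          grid[[gi]], seed = seed + gi)
      auc_score(predict_prob(m, X[te, , drop = FALSE]), y[te])
    }, 0)
    mean(aucs, na.rm = TRUE)
  }, 0)
  grid[[which.max(mean_auc)]]
}

#' Repeated cross-validated response prediction
#'
#' The full prediction process, repeated: per repetition the sample is
#' reshuffled into stratified 3-fold cross-validation splits with a
#' repetition-specific seed derived from `seed`; within each training
#' split hyper-parameters are chosen by inner-CV grid search (AUC as the
#' selection metric) unless `param_grid = NULL`, which mirrors the
#' default-parameter mode; the held-out predictions are pooled into one
#' AUC per repetition. Patients with missing features are dropped (and
#' counted). The published design uses 5000 repetitions; tests use far
#' fewer.
#'
#' @param X feature matrix (rows = patients).
#' @param y binary responder labels.
#' @param family one of [classifier_families()].
#' @param param_grid list of parameter lists to search, `NULL` for
#'   default-parameter mode, or `"default"` for [default_grid()].
#' @param repetitions number of repetitions of the whole process.
#' @param seed master seed; the full report is reproducible from it.
#' @param n_folds outer folds (3 in the published design).
#' @param inner_folds folds of the inner selection CV.
#' @param importance also compute averaged feature importances (small
#'   extra cost for the perceptron)?
#' @return Object of class `tiic_model_report`: `family`,
#'   `auc_per_repetition`, `mean_auc`, `ci95`, `chosen_params`
#'   (modal selection), `importances`, `n_dropped`, `seed`.
#' @export
fit_predict_cv <- function(X, y, family, param_grid = NULL,
                           repetitions = 200L, seed = 1L, n_folds = 3L,
                           inner_folds = 3L, importance = TRUE) {
  family <- match.arg(family, classifier_families())
  X <- as.matrix(X); storage.mode(X) <- "double"
  y <- as.numeric(y)
  keep <- complete.cases(X) & !is.na(y)
  n_dropped <- sum(!keep)
  if (n_dropped) message(n_dropped, " incomplete patient(s) dropped")
  X <- X[keep, , drop = FALSE]; y <- y[keep]
  stopifnot(all(y %in% c(0, 1)))
  if (identical(param_grid, "default")) param_grid <- default_grid(family)

  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(seed)
  rep_seeds <- sample.int(.Machine$integer.max - 1L, repetitions)

  aucs <- numeric(repetitions)
  imp_sum <- setNames(numeric(ncol(X)),
                      colnames(X) %||% paste0("f", seq_len(ncol(X))))
  n_imp <- 0L
  param_tally <- list()
  for (r in seq_len(repetitions)) {
    set.seed(rep_seeds[r])
    fold <- .stratified_folds(y, n_folds)
    pred <- numeric(length(y))
    for (f in seq_len(n_folds)) {
      tr <- fold != f
      params <- .select_params(X[tr, , drop = FALSE], y[tr], family,
                               param_grid, inner_folds,
                               seed = rep_seeds[r] %% 1000000L + f)
      key <- paste(deparse(params, control = NULL), collapse = "")
      param_tally[[key]] <- (param_tally[[key]] %||% 0L) + 1L
      attr(param_tally[[key]], "params") <- params
      m <- fit_classifier(family, X[tr, , drop = FALSE], y[tr], params,
                          seed = rep_seeds[r] %% 1000000L + 7L * f)
      pred[!tr] <- predict_prob(m, X[!tr, , drop = FALSE])
      if (importance) {
        imp <- feature_importance(m, X[tr, , drop = FALSE], y[tr],
                                  seed = rep_seeds[r] %% 1000000L + f)
        imp_sum <- imp_sum + imp
        n_imp <- n_imp + 1L
      }
    }
    aucs[r] <- auc_score(pred, y)
  }
  counts <- vapply(param_tally, as.integer, 0L)
  chosen <- attr(param_tally[[which.max(counts)]], "params")
  structure(list(
    family = family,
    auc_per_repetition = aucs,
    mean_auc = mean(aucs),
    ci95 = quantile(aucs, c(0.025, 0.975), names = FALSE),
    chosen_params = chosen,
    importances = if (n_imp > 0) imp_sum / n_imp else NULL,
    n_dropped = n_dropped, repetitions = repetitions, seed = seed),
    class = "tiic_model_report")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.tiic_model_report <- function(x, ...) {
  cat("<tiic_model_report>", x$family, "-", x$repetitions,
      "repetitions\n  mean AUC", round(x$mean_auc, 3),
      sprintf("(95%% CI %.3f-%.3f)\n", x$ci95[1], x$ci95[2]))
  if (!is.null(x$importances)) {
    cat("  importances:\n")
    print(round(x$importances, 3))
  }
  invisible(x)
}
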