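test_that("univariate screening reports OR, CI and direction", {
  set.seed(61)
  n <- 60
  X <- data.frame(up = rnorm(n), flat = rep(2, n), noise = rnorm(n))
  y <- rbinom(n, 1, plogis(-0.5 + 1.2 * X$up))
  tab <- screen_features(X, y)
  expect_equal(tab$method[tab$feature == "flat"], "degenerate")
  expect_true(is.na(tab$or[tab$feature == "flat"]))
  expect_equal(tab$direction[tab$feature == "up"], "positive")
  expect_gt(tab$or[tab$feature == "up"], 1)
  expect_lt(tab$p[tab$feature == "up"], 0.05)
  expect_error(screen_features(X, rep(1, n)), ">= 2")
})

test_that("screening matches the closed-form two-point logistic fit", {
  # balanced anti-symmetric design: responders at +1, non-responders at -1,
  # with one crossover pair so the MLE is finite; closed form:
  # beta = log(9) / 2 for 9:1 vs 1:9 split at the two design points
  x <- rep(c(1, -1), each = 10)
  y <- c(rep(1, 9), 0, rep(0, 9), 1)
  tab <- screen_features(data.frame(x = x), y)
  expect_equal(log(tab$or), log(81) / 2, tolerance = 1e-4)
  expect_gt(tab$or, 1)
  expect_equal(tab$method, "mle")
})

test_that("complete separation falls back to a labelled penalised fit", {
  x <- c(rnorm(10, -3), rnorm(10, 3))
  y <- rep(c(0, 1), each = 10)
  tab <- screen_features(data.frame(x = x), y)
  expect_equal(tab$method, "penalised")
  expect_true(is.finite(tab$or))
  expect_gt(tab$or, 1)
})

test_that("label-permuted features yield calibrated screening p-values", {
  set.seed(62)
  n <- 50
  x <- rnorm(n); y <- rbinom(n, 1, 0.4)
  ps <- replicate(400, screen_features(data.frame(x = x),
                                       sample(y))$p)
  expect_lt(abs(mean(ps < 0.05, na.rm = TRUE) - 0.05), 0.035)
})

test_that("AUC is rank-based with label-flip anti-symmetry", {
  set.seed(63)
  s <- rnorm(30); y <- rbinom(30, 1, 0.5)
  expect_equal(auc_score(s, y) + auc_score(s, 1 - y), 1)
  expect_equal(auc_score(c(0.1, 0.9), c(0, 1)), 1)
  expect_error(auc_score(s, rep(1, 30)), "both classes")
})

test_that("the harness is reproducible under a fixed master seed", {
  set.seed(64)
  X <- matrix(rnorm(40 * 4), 40, 4)
  y <- rep(c(0, 1), each = 20)
  r1 <- fit_predict_cv(X, y, "extra_trees", NULL, repetitions = 8,
                       seed = 99)
  r2 <- fit_predict_cv(X, y, "extra_trees", NULL, repetitions = 8,
                       seed = 99)
  expect_identical(r1$auc_per_repetition, r2$auc_per_repetition)
  expect_identical(r1$importances, r2$importances)
  expect_equal(r1$mean_auc, mean(r1$auc_per_repetition))
  expect_equal(length(r1$auc_per_repetition), 8)
  r3 <- fit_predict_cv(X, y, "extra_trees", NULL, repetitions = 8,
                       seed = 100)
  expect_false(identical(r1$auc_per_repetition, r3$auc_per_repetition))
})

test_that("the grid-search path selects and reports parameters", {
  set.seed(65)
  X <- matrix(rnorm(48 * 3), 48, 3); colnames(X) <- c("a", "b", "c")
  y <- as.numeric(X[, 1] + rnorm(48, 0, 0.4) > 0)
  grid <- list(list(n_trees = 25L, max_depth = 1L),
               list(n_trees = 50L, max_depth = 3L))
  r <- fit_predict_cv(X, y, "extra_trees", grid, repetitions = 3,
                      seed = 7)
  expect_true(r$chosen_params$n_trees %in% c(25L, 50L))
  expect_gt(r$mean_auc, 0.7)
  # importances behave as a normalised distribution led by the signal
  expect_equal(sum(r$importances), 1, tolerance = 1e-9)
  expect_equal(names(which.max(r$importances)), "a")
})

test_that("incomplete patients are dropped and scarce classes error", {
  X <- matrix(rnorm(30 * 2), 30, 2)
  X[3, 1] <- NA
  y <- rep(c(0, 1), 15)
  expect_message(r <- fit_predict_cv(X, y, "adaboost", NULL,
                                     repetitions = 2, seed = 1),
                 "1 incomplete")
  expect_equal(r$n_dropped, 1)
  y2 <- c(rep(0, 28), 1, 1) # two positives cannot stratify 3 folds
  expect_error(fit_predict_cv(matrix(rnorm(60), 30, 2), y2, "adaboost",
                              NULL, repetitions = 2, seed = 1),
               "fewer members")
})

test_that("tree importances are normalised and symmetric under noise", {
  set.seed(66)
  X <- matrix(rnorm(200 * 4), 200, 4)
  y <- rbinom(200, 1, 0.5)
  for (fam in c("extra_trees", "gradient_boosting", "adaboost")) {
    m <- fit_classifier(fam, X, y, seed = 3)
    imp <- feature_importance(m)
    expect_equal(sum(imp), 1, tolerance = 1e-9)
    expect_true(all(imp >= 0))
  }
  # pure-noise features spread importance roughly evenly (extra-trees)
  imps <- rowMeans(replicate(10, {
    yy <- rbinom(200, 1, 0.5)
    feature_importance(fit_classifier("extra_trees", X, yy,
                                      seed = sample.int(1e6, 1)))
  }))
  expect_true(all(abs(imps - 0.25) < 0.1))
})

test_that("a planted feature dominates importance in every family", {
  set.seed(67)
  X <- matrix(rnorm(60 * 4), 60, 4)
  y <- rep(c(0, 1), each = 30)
  X[, 2] <- y + rnorm(60, 0, 0.15)
  for (fam in classifier_families()) {
    m <- fit_classifier(fam, X, y, seed = 5)
    imp <- feature_importance(m, X, y, seed = 5)
    expect_equal(which.max(imp), 2L)
  }
})

test_that("the combined-signature mode runs the identical harness", {
  set.seed(68)
  n <- 45
  X4 <- matrix(rnorm(n * 4), n, 4,
               dimnames = list(NULL, signature_features()$feature))
  X7 <- cbind(X4, ebv = rbinom(n, 1, 0.2), mmr = rbinom(n, 1, 0.15),
              cps = rexp(n, 0.1))
  y <- rbinom(n, 1, plogis(X4[, 1]))
  r4 <- fit_predict_cv(X4, y, "gradient_boosting", NULL, repetitions = 4,
                       seed = 11, importance = FALSE)
  r7 <- fit_predict_cv(X7, y, "gradient_boosting", NULL, repetitions = 4,
                       seed = 11, importance = FALSE)
  expect_length(r7$auc_per_repetition, 4)
  expect_true(is.finite(r7$mean_auc))
  expect_equal(r7$ci95, unname(quantile(r7$auc_per_repetition,
                                        c(0.025, 0.975))))
  expect_false(identical(r4$mean_auc, r7$mean_auc))
})
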